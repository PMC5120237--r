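test_that("the generated pilot has the canonical shape and valid ratings", {
  gen <- generateRatings(generatorConfig(seed = 8))
  trip <- ratingTriplets(gen$data)
  expect_equal(nRatings(gen$data), 16920L)
  expect_equal(nUsers(gen$data), 846L)
  expect_equal(nMessages(gen$data), 261L)
  expect_true(all(trip$rating %in% 1:5))
  perUser <- table(trip$user)
  expect_true(all(perUser == 20L))
  ## no duplicate pairs by construction
  expect_equal(anyDuplicated(paste(trip$user, trip$message)), 0L)
  gen2 <- generateRatings(generatorConfig(seed = 8))
  expect_identical(trip, ratingTriplets(gen2$data))
  gen3 <- generateRatings(generatorConfig(seed = 9))
  expect_false(identical(trip, ratingTriplets(gen3$data)))
  expect_error(generatorConfig(nMessages = 10, ratingsPerUser = 11),
               "must not exceed")
})

test_that("a degenerate generator pins every rating at the offset", {
  gc0 <- generatorConfig(nUsers = 15, nMessages = 10, ratingsPerUser = 6,
                         latentDim = 1, factorScale = 1e-9, noiseSd = 0,
                         offset = 3, seed = 2)
  gen <- generateRatings(gc0)
  expect_true(all(ratingTriplets(gen$data)$rating == 3))
})

test_that("observed ratings track the true scores more closely as noise falls", {
  corAt <- function(noise) {
    gen <- generateRatings(generatorConfig(nUsers = 150, nMessages = 60,
                                           ratingsPerUser = 15,
                                           noiseSd = noise, seed = 5))
    trip <- ratingTriplets(gen$data)
    truth <- rowSums(gen$userFactors[trip$user, ] *
                       gen$itemFactors[trip$message, ]) + gen$offset
    cor(truth, trip$rating)
  }
  c1 <- corAt(1.2); c2 <- corAt(0.5); c3 <- corAt(0.1)
  expect_gt(c1, 0)
  expect_gt(c2, c1)
  expect_gt(c3, c2)
})

test_that("block randomization reproduces the composition exactly", {
  coh <- generateCohort(cohortConfig(nParticipants = 120, block = c(7, 3), seed = 3))
  expect_equal(as.integer(table(coh$participants$arm)[c("INTERVENTION", "COMPARISON")]),
               c(84L, 36L))
  coh2 <- generateCohort(cohortConfig(nParticipants = 9, block = c(2, 1), seed = 3))
  expect_equal(sum(coh2$participants$arm == "INTERVENTION"), 6L)
  ## composition holds within every complete block
  arm <- coh$participants$arm
  blocks <- split(arm, rep(seq_len(12), each = 10))
  expect_true(all(vapply(blocks, function(b) sum(b == "COMPARISON") == 3L,
                         logical(1))))
})

test_that("a null arm effect leaves latent preferences exchangeable across arms", {
  x <- c(); g <- c()
  for (s in 1:8) {
    coh <- generateCohort(cohortConfig(nParticipants = 60, armEffect = 0, seed = s))
    x <- c(x, coh$userFactors[, 1])
    g <- c(g, coh$participants$arm)
  }
  expect_gt(t.test(x[g == "INTERVENTION"], x[g == "COMPARISON"])$p.value, 0.01)
})

test_that("follow-up simulation honours its rate and effect parameters", {
  coh <- generateCohort(cohortConfig(nParticipants = 60, seed = 4))
  none <- simulateFollowup(coh, followupConfig(followupRate = 1, quitBase = 0,
                                               ladderUpBase = 0),
                           armEffect = 0, seed = 1)
  expect_true(all(none$completed))
  expect_true(all(!none$quitOneDay))
  expect_identical(none$followupStage, none$baselineStage)
  zero <- simulateFollowup(coh, followupConfig(followupRate = 0), seed = 1)
  expect_equal(sum(zero$completed), 0L)
  ## a strongly positive effect raises the intervention quit proportion
  big <- generateCohort(cohortConfig(nParticipants = 2000, armEffect = 2, seed = 5))
  wins <- vapply(1:10, function(s) {
    fu <- simulateFollowup(big, followupConfig(followupRate = 1), seed = s)
    mean(fu$quitOneDay[fu$arm == "INTERVENTION"]) >
      mean(fu$quitOneDay[fu$arm == "COMPARISON"])
  }, logical(1))
  expect_true(all(wins))
})
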