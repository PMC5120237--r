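test_that("a single stage-matched unsent message is forced for either policy", {
  lib <- tinyLib()                      # m3 carries every stage
  V <- rbind(m1 = c(1, 0), m2 = c(0, 1), m3 = c(0.5, 0.5))
  model <- manualBPMF(V)
  st <- newSession("u", "THINKING")
  st <- sendMessage(st, "m1"); st <- sendMessage(st, "m3")
  expect_equal(selectNext(st, perspectPolicy(model), lib)$message, "m2")
  expect_equal(selectNext(st, ruleBasedPolicy(4), lib)$message, "m2")
})

test_that("the recommender picks the exhaustive argmax with id tie-breaking", {
  V <- rbind(m01 = c(1, 0), m02 = c(0.4, 0.2), m03 = c(-1, 0.5),
             m04 = c(0.8, 0.1), m05 = c(1, 0))
  lib <- MessageLibrary(rownames(V), text = rownames(V),
                        source = rep("EXPERT", 5),
                        stages = replicate(5, readinessStages(), simplify = FALSE))
  model <- manualBPMF(V, offset = 3)
  st <- newSession("u", "THINKING")
  st@userFactors <- matrix(c(1, 0), 1, 2)
  scores <- drop(V %*% c(1, 0)) + 3
  best <- names(scores)[order(-pmin(5, pmax(1, scores)), names(scores))][1]
  sel <- selectNext(st, perspectPolicy(model), lib)
  expect_equal(sel$message, best)
  expect_equal(sel$message, "m01")       # ties with m05 resolve to the lower id
  expect_equal(sel$predicted, 4)
})

test_that("sessions never repeat a message and respect a satisfiable stage filter", {
  ## 40 of 60 messages carry the user's stage: the filter is always satisfiable
  stages <- c(replicate(40, c("THINKING"), simplify = FALSE),
              replicate(20, c("ALREADY_QUIT"), simplify = FALSE))
  lib <- MessageLibrary(sprintf("m%02d", 1:60), text = paste("msg", 1:60),
                        source = rep("PEER", 60), stages = stages)
  gen <- generateRatings(generatorConfig(nUsers = 40, nMessages = 60,
                                         ratingsPerUser = 15, seed = 3), lib)
  model <- fitBPMF(gen$data, latentDim = 2, nSamples = 10, burnIn = 5, seed = 1)
  orc <- latentRatingOracle(c(0.5, -0.2), gen$itemFactors, seed = 2)
  thinkingIds <- sprintf("m%02d", 1:40)
  for (pol in list(perspectPolicy(model), ruleBasedPolicy(9))) {
    st <- runSession("u", "THINKING", pol, lib, orc, n = 30)
    expect_equal(anyDuplicated(st@sent), 0L)
    expect_length(st@sent, 30)
    expect_true(all(st@sent %in% thinkingIds))
    expect_equal(nrow(sessionLog(st)), 30)
  }
})

test_that("the filter relaxes outward over the ladder before giving up", {
  lib <- MessageLibrary(c("a", "b", "c"), text = c("a", "b", "c"),
                        source = rep("EXPERT", 3),
                        stages = list("NOT_THINKING", "SET_QUIT_DATE", "ALREADY_QUIT"))
  st <- newSession("u", "THINKING")
  ## exact stage has no message; the adjacent levels offer a and b
  sel <- selectNext(st, ruleBasedPolicy(1), lib)
  expect_true(sel$message %in% c("a", "b"))
  st2 <- sendMessage(sendMessage(st, "a"), "b")
  expect_equal(selectNext(st2, ruleBasedPolicy(1), lib)$message, "c")
  st3 <- sendMessage(st2, "c")
  expect_error(selectNext(st3, ruleBasedPolicy(1), lib), "exhausted")
})

test_that("the comparator's stream is reproducible and ignores ratings", {
  lib <- generateLibrary(nMessages = 50, seed = 5)
  orcHigh <- function(message, day) 5
  orcLow <- function(message, day) 1
  s1 <- runSession("u", "THINKING", ruleBasedPolicy(7), lib, orcHigh, n = 20)
  s2 <- runSession("u", "THINKING", ruleBasedPolicy(7), lib, orcLow, n = 20)
  s3 <- runSession("u", "THINKING", ruleBasedPolicy(8), lib, orcLow, n = 20)
  expect_identical(s1@sent, s2@sent)     # ratings never steer the comparator
  expect_false(identical(s1@sent, s3@sent))
})

test_that("rating bookkeeping rejects unsent or repeated ratings", {
  lib <- tinyLib()
  st <- newSession("u", "THINKING")
  pol <- ruleBasedPolicy(1)
  expect_error(recordRating(st, "m1", 4, pol), "unsent")
  st <- sendMessage(st, "m1")
  st <- recordRating(st, "m1", 4, pol)
  expect_error(recordRating(st, "m1", 2, pol), "already rated")
  expect_error(sendMessage(st, "m1"), "already sent")
  expect_error(recordRating(sendMessage(st, "m2"), "m2", 9, pol), "1..5")
})

test_that("a high rating raises predictions for similar messages", {
  V <- rbind(m1 = 1, m2 = 1, m3 = -1)
  model <- manualBPMF(V, userLambda = matrix(2, 1, 1), offset = 3)
  lib <- MessageLibrary(rownames(V), text = rownames(V),
                        source = rep("PEER", 3),
                        stages = replicate(3, "THINKING", simplify = FALSE))
  st <- newSession("u", "THINKING")
  before <- predictNewUser(model, inferNewUser(model, character(0), numeric(0)), "m2")
  st <- sendMessage(st, "m1")
  st <- recordRating(st, "m1", 5, perspectPolicy(model))
  after <- predictNewUser(model, st@userFactors, "m2")
  expect_gt(after, before)               # same-direction item moves up
  expect_lt(predictNewUser(model, st@userFactors, "m3"), before)
})

test_that("a full session on the canonical library sends 30 of 261 messages", {
  lib <- generateLibrary(seed = 6)
  gen <- generateRatings(generatorConfig(nUsers = 150, nMessages = 261,
                                         ratingsPerUser = 20, seed = 6), lib)
  model <- fitBPMF(gen$data, latentDim = 2, nSamples = 10, burnIn = 5, seed = 2)
  constOrc <- function(message, day) 3
  st <- runSession("u", "SET_QUIT_DATE", perspectPolicy(model), lib, constOrc, n = 30)
  expect_length(st@sent, 30)
  expect_length(setdiff(messageIds(lib), st@sent), 231)
  ## with every observed rating at 3, late predictions hover near 3
  lg <- sessionLog(st)
  expect_lt(abs(tail(lg$predicted, 1) - 3), 0.5)
})
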