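constantDataset <- function(nUsers = 20, nMessages = 10, rating = 3) {
  grid <- expand.grid(user = sprintf("u%02d", seq_len(nUsers)),
                      message = sprintf("m%02d", seq_len(nMessages)),
                      stringsAsFactors = FALSE)
  grid$rating <- rating
  RatingDataset(grid)
}

test_that("constant ratings produce predictions at the constant", {
  data <- constantDataset()
  fit <- fitBPMF(data, latentDim = 2, nSamples = 60, burnIn = 20, seed = 1)
  pred <- predictRating(fit, ratingTriplets(data)$user, ratingTriplets(data)$message)
  expect_true(all(pred >= 2.9 & pred <= 3.1))
})

test_that("the sampler is deterministic per seed", {
  gen <- generateRatings(generatorConfig(nUsers = 25, nMessages = 15,
                                         ratingsPerUser = 8, seed = 2))
  f1 <- fitBPMF(gen$data, latentDim = 2, nSamples = 10, burnIn = 5, seed = 7)
  f2 <- fitBPMF(gen$data, latentDim = 2, nSamples = 10, burnIn = 5, seed = 7)
  expect_identical(f1@userFactors, f2@userFactors)
  expect_identical(f1@itemFactors, f2@itemFactors)
  f3 <- fitBPMF(gen$data, latentDim = 2, nSamples = 10, burnIn = 5, seed = 8)
  expect_false(identical(f1@userFactors, f3@userFactors))
})

test_that("an unrated indexed user or message is refused with cold-start advice", {
  d <- RatingDataset(data.frame(user = "u1", message = "m1", rating = 4),
                     userIds = c("u1", "u2"), messageIds = "m1")
  expect_error(fitBPMF(d, latentDim = 1), "cold-start")
})

test_that("prediction is the posterior-mean inner product, clipped", {
  V <- rbind(m1 = c(1, 0), m2 = c(3, 0), m3 = c(-2, 1))
  fit <- manualBPMF(V, offset = 3)
  fit@userFactors[1, 1, ] <- c(1, 0)
  expect_equal(predictRating(fit, "u-train", "m1"), 4)
  fit@userFactors[1, 1, ] <- c(3, 0)
  expect_equal(predictRating(fit, "u-train", "m2"), 5)   # 12 clipped to 5
  expect_error(predictRating(fit, "u-train", "nope"), "unknown message")
  expect_error(predictRating(fit, "nope", "m1"), "unknown user")
})

test_that("multi-sample predictions equal the per-sample loop average", {
  gen <- generateRatings(generatorConfig(nUsers = 20, nMessages = 12,
                                         ratingsPerUser = 6, seed = 3))
  fit <- fitBPMF(gen$data, latentDim = 3, nSamples = 9, burnIn = 4, seed = 5)
  trip <- head(ratingTriplets(gen$data), 25)
  uidx <- match(trip$user, userIds(fit)); midx <- match(trip$message, messageIds(fit))
  manual <- sapply(seq_len(nrow(trip)), function(i) {
    per <- sapply(1:9, function(s)
      sum(fit@userFactors[s, uidx[i], ] * fit@itemFactors[s, midx[i], ]))
    min(5, max(1, mean(per) + fit@offset))
  })
  expect_equal(predictRating(fit, trip$user, trip$message), manual, tolerance = 1e-12)
})

test_that("cold-start inference falls back to the offset and shrinks correctly", {
  V <- rbind(m1 = c(2), m2 = c(2), m3 = c(2))
  lam <- 1.7; mu <- 0; a <- 2.5
  fit <- manualBPMF(V, userLambda = matrix(lam, 1, 1), userMu = mu,
                    offset = 3, alpha = a)
  ## nothing observed: the factor is zero and every prediction is the offset
  uf0 <- inferNewUser(fit, character(0), numeric(0))
  expect_equal(uf0, matrix(0, 1, 1))
  expect_equal(predictNewUser(fit, uf0, c("m1", "m3")), c(3, 3))
  ## scalar ridge closed form: (lam*mu + a * sum(v*y)) / (lam + a * sum(v^2))
  obs <- c(m1 = 5, m2 = 4)
  y <- obs - 3
  want <- (lam * mu + a * sum(2 * y)) / (lam + a * sum(4, 4))
  uf <- inferNewUser(fit, names(obs), obs)
  expect_equal(uf[1, 1], want, tolerance = 1e-12)
  ## prediction sits between the offset and the observed ratings (shrinkage)
  p <- predictNewUser(fit, uf, "m3")
  expect_gt(p, 3); expect_lt(p, 5)
})

test_that("held-out error vanishes on noise-free continuous ratings", {
  gc0 <- generatorConfig(nUsers = 120, nMessages = 60, ratingsPerUser = 20,
                         latentDim = 2, factorScale = 0.6, noiseSd = 0, seed = 6)
  gen <- generateRatings(gc0, ordinal = FALSE)
  trip <- ratingTriplets(gen$data)
  train <- sprintf("u%04d", 1:100); test <- sprintf("u%04d", 101:120)
  trainTrip <- trip[trip$user %in% train, ]
  td <- RatingDataset(trainTrip, userIds = train,
                      messageIds = unique(trainTrip$message))
  fit <- fitBPMF(td, latentDim = 2, alpha = 50, nSamples = 40, burnIn = 20,
                 seed = 6)
  errs <- c()
  for (u in test) {
    tri <- trip[trip$user == u, ]
    keep <- tri$message %in% messageIds(fit)
    tri <- tri[keep, ]
    obs <- seq_len(nrow(tri) - 4); tst <- nrow(tri) - 3:0
    uf <- inferNewUser(fit, tri$message[obs], tri$rating[obs])
    errs <- c(errs, predictNewUser(fit, uf, tri$message[tst]) - tri$rating[tst])
  }
  expect_lte(sqrt(mean(errs^2)), 0.15)
})

test_that("a model archive round-trips through JSON", {
  gen <- generateRatings(generatorConfig(nUsers = 15, nMessages = 10,
                                         ratingsPerUser = 5, seed = 4))
  fit <- fitBPMF(gen$data, latentDim = 2, nSamples = 5, burnIn = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  saveBPMF(fit, path)
  back <- readBPMF(path)
  expect_equal(back@userFactors, fit@userFactors)
  expect_equal(back@userLambda, fit@userLambda)
  expect_equal(predictRating(back, "u0001", "m001"),
               predictRating(fit, "u0001", "m001"))
})
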