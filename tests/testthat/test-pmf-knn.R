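test_that("ALS keeps the penalized objective monotone and fits constant data", {
  gen <- generateRatings(generatorConfig(nUsers = 30, nMessages = 20,
                                         ratingsPerUser = 10, seed = 5))
  fit <- fitPMF(gen$data, latentDim = 2, lambda = 1, seed = 2)
  expect_true(all(diff(fit@objective) <= 1e-8))
  const <- RatingDataset(expand.grid(user = paste0("u", 1:10),
                                     message = paste0("m", 1:8),
                                     stringsAsFactors = FALSE) |>
                           transform(rating = 3))
  cf <- fitPMF(const, latentDim = 2, lambda = 1, seed = 1)
  preds <- predictRating(cf, "u1", paste0("m", 1:8))
  expect_true(all(abs(preds - 3) < 0.05))
})

test_that("PMF matches BPMF held-out error on the shared benchmark", {
  gen <- generateRatings(generatorConfig(nUsers = 150, nMessages = 60,
                                         ratingsPerUser = 20, latentDim = 2,
                                         seed = 21))
  trip <- ratingTriplets(gen$data)
  train <- sprintf("u%04d", 1:120); test <- sprintf("u%04d", 121:150)
  trainTrip <- trip[trip$user %in% train, ]
  td <- RatingDataset(trainTrip, userIds = train,
                      messageIds = unique(trainTrip$message))
  holdout <- function(alg) {
    model <- alg$fit(td, 5)
    errs <- c()
    for (u in test) {
      tri <- trip[trip$user == u, ]
      pr <- alg$predictNew(model, u, tri$message[1:16], tri$rating[1:16],
                           tri$message[17:20])
      errs <- c(errs, pr - tri$rating[17:20])
    }
    sqrt(mean(errs^2))
  }
  rb <- holdout(algoBPMF(latentDim = 2, nSamples = 30, burnIn = 20))
  rp <- holdout(algoPMF(latentDim = 2, lambda = 2))
  expect_lt(abs(rp - rb), 0.1 * rb)
})

test_that("a perfect neighbour dominates the K-NN prediction", {
  ## users a and b agree exactly on m1..m4 (mean 3); b also rated m5
  df <- rbind(data.frame(user = "a", message = paste0("m", 1:4),
                         rating = c(3, 3, 5, 1)),
              data.frame(user = "b", message = paste0("m", 1:5),
                         rating = c(3, 3, 5, 1, 3)))
  d <- RatingDataset(df)
  expect_equal(knnPredict(d, "a", "m5", k = 5, minOverlap = 2), 3)
})

test_that("K-NN falls back to message then global means", {
  df <- rbind(data.frame(user = "a", message = "m1", rating = 5),
              data.frame(user = "b", message = c("m2", "m3"), rating = c(2, 4)),
              data.frame(user = "c", message = c("m2", "m3"), rating = c(4, 4)))
  d <- RatingDataset(df)
  ## no user co-rates anything with a -> message mean of m2
  expect_equal(knnPredict(d, "a", "m2"), 3)
  ## unrated message -> global mean
  gm <- mean(df$rating[df$user != "a"])
  d2 <- RatingDataset(df, messageIds = c("m1", "m2", "m3", "m9"))
  expect_equal(knnPredict(d2, "a", "m9"), gm)
})

test_that("K-NN equals an exhaustive hand computation on the toy matrix", {
  m <- toyMatrix()
  d <- toyDataset(m)
  k <- 2; minOv <- 2
  oracle <- function(user, msg) {
    ui <- match(user, rownames(m)); mj <- match(msg, colnames(m))
    others <- setdiff(seq_len(nrow(m)), ui)
    sims <- sapply(others, function(o) {
      common <- which(m[ui, ] != 0 & m[o, ] != 0)
      if (length(common) < max(2, minOv)) return(NA_real_)
      s <- suppressWarnings(cor(m[ui, common], m[o, common]))
      if (is.finite(s)) s else NA_real_
    })
    raters <- others[m[others, mj] != 0 & !is.na(sims)]
    target <- mean(m[ui, ][m[ui, ] != 0])
    if (length(raters)) {
      simsR <- sims[match(raters, others)]
      ord <- raters[order(-simsR, raters)]
      top <- head(ord, k)
      w <- sims[match(top, others)]
      if (sum(abs(w)) > 0) {
        dev <- sapply(top, function(o) m[o, mj] - mean(m[o, ][m[o, ] != 0]))
        return(min(5, max(1, target + sum(w * dev) / sum(abs(w)))))
      }
    }
    allRaters <- which(m[, mj] != 0 & seq_len(nrow(m)) != ui)
    if (length(allRaters)) return(min(5, max(1, mean(m[allRaters, mj]))))
    min(5, max(1, mean(m[m != 0 & row(m) != ui])))
  }
  for (case in list(c("u1", "m3"), c("u2", "m6"), c("u4", "m5"), c("u5", "m2"))) {
    expect_equal(knnPredict(d, case[1], case[2], k = k, minOverlap = minOv),
                 oracle(case[1], case[2]), info = paste(case, collapse = "/"))
  }
})

test_that("mean baselines recompute exactly with fallbacks", {
  d <- RatingDataset(data.frame(user = c("a", "a", "b"),
                                message = c("m1", "m2", "m1"),
                                rating = c(4, 4, 5)),
                     messageIds = c("m1", "m2", "m3"))
  expect_equal(baselinePredict(d, "GLOBAL_MEAN"), 13 / 3)
  expect_equal(baselinePredict(d, "MESSAGE_MEAN", message = c("m1", "m3")),
               c(4.5, 13 / 3))
  trip <- ratingTriplets(toyDataset())
  um <- baselinePredict(toyDataset(), "USER_MEAN", user = unique(trip$user))
  want <- vapply(unique(trip$user),
                 function(u) mean(trip$rating[trip$user == u]), numeric(1))
  expect_equal(um, unname(want))
})
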