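test_that("user folds partition the users with near-equal sizes", {
  f <- splitUsers(sprintf("u%03d", 1:100), 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  f846 <- splitUsers(sprintf("u%03d", 1:846), 5, seed = 1)
  expect_equal(sort(as.integer(table(f846)), decreasing = TRUE),
               c(170L, 169L, 169L, 169L, 169L))
  expect_setequal(names(f846), sprintf("u%03d", 1:846))
  expect_identical(f846, splitUsers(sprintf("u%03d", 1:846), 5, seed = 1))
  expect_false(identical(f846, splitUsers(sprintf("u%03d", 1:846), 5, seed = 2)))
  expect_error(splitUsers(c("a", "b"), 5), "at least as many users")
})

test_that("per-user rating folds keep observed and test sets disjoint", {
  cfg <- protocolConfig()
  folds <- splitUserRatings(20, cfg, seed = 3)
  expect_length(folds, 5)
  allTests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(allTests, 1:20)          # test folds partition the ratings
  for (f in folds) {
    expect_length(f$test, 4)
    for (s in c("5", "10", "16")) {
      expect_length(f$observed[[s]], as.integer(s))
      expect_length(intersect(f$observed[[s]], f$test), 0)
    }
    ## the largest budget is forced to be the exact complement of the test fold
    expect_setequal(f$observed[["16"]], setdiff(1:20, f$test))
  }
  expect_error(splitUserRatings(19, cfg, user = "u9"), "u9")
  expect_error(splitUserRatings(20, protocolConfig(observedSizes = c(5, 17)),
                                user = "u9"), "budget")
})

test_that("grid search finds interior optima and extends past boundaries", {
  const <- RatingDataset(transform(expand.grid(user = paste0("u", 1:12),
                                               message = paste0("m", 1:8),
                                               stringsAsFactors = FALSE),
                                   rating = 3))
  val <- subsetUsers(const, paste0("u", 9:12))
  train <- subsetUsers(const, paste0("u", 1:8))
  ## a one-parameter family predicting the constant mu everywhere
  makeAlgo <- function(params) list(
    name = "CONST", fit = function(train, seed) params$mu,
    predictNew = function(model, user, om, or, targets) rep(model, length(targets)))
  one <- gridSearch(makeAlgo, list(mu = 3), train, val, seed = 1)
  expect_equal(one$params$mu, 3)
  expect_equal(one$nExtensions, 0L)
  interior <- gridSearch(makeAlgo, list(mu = c(2.5, 3, 3.5)), train, val, seed = 1)
  expect_equal(interior$params$mu, 3)
  expect_equal(interior$nExtensions, 0L)
  ## optimum one step outside the initial range: one extension suffices
  ext <- gridSearch(makeAlgo, list(mu = c(2, 2.5, 3)), train, val, seed = 1)
  expect_equal(ext$params$mu, 3)
  expect_equal(ext$nExtensions, 1L)
  expect_false(ext$boundary)
  ## full-grid oracle over the extended range agrees
  cand <- c(2, 2.5, 3, 3.5)
  oracleBest <- cand[which.min(abs(cand - 3))]
  expect_equal(ext$params$mu, oracleBest)
  ## unreachable optimum trips the extension cap with a warning
  expect_warning(
    capped <- gridSearch(makeAlgo, list(mu = c(0.5, 1)), train, val,
                         seed = 1, maxExtensions = 1),
    "extension cap")
  expect_true(capped$boundary)
})

test_that("the protocol emits one fully indexed cell per combination", {
  gen <- generateRatings(generatorConfig(nUsers = 40, nMessages = 30,
                                         ratingsPerUser = 20, seed = 7))
  cfg <- protocolConfig(seed = 7)
  report <- runProtocol(list(algoBaseline("GLOBAL_MEAN"),
                             algoBaseline("USER_MEAN")), gen$data, cfg)
  expect_equal(nrow(report), 2 * 5 * 3 * 3)
  expect_equal(anyDuplicated(report[c("algorithm", "fold", "rep", "observedSize")]), 0L)
  expect_true(all(is.finite(report$rmse)) && all(report$rmse >= 0))
  expect_true(all(report$n == report$nUsers * 5 * 4))
})

test_that("an oracle that returns the true rating scores zero error everywhere", {
  gen <- generateRatings(generatorConfig(nUsers = 25, nMessages = 25,
                                         ratingsPerUser = 20, seed = 9))
  trip <- ratingTriplets(gen$data)
  lookup <- setNames(trip$rating, paste(trip$user, trip$message))
  oracleAlg <- list(name = "ORACLE", fit = function(train, seed) NULL,
                    predictNew = function(model, user, om, or, targets)
                      unname(lookup[paste(user, targets)]))
  report <- runProtocol(list(oracleAlg), gen$data,
                        protocolConfig(nRepeats = 1, seed = 2))
  expect_true(all(report$rmse == 0))
  expect_true(all(report$ndcg == 1))
})

test_that("paired comparisons follow the textbook t computation", {
  cells <- expand.grid(fold = 1:5, rep = 1, observedSize = 5)
  mk <- function(name, vals) cbind(data.frame(algorithm = name), cells,
                                   rmse = vals, kendallTauB = NA, ndcg = NA)
  ## identical vectors: no difference, t = 0, p = 1
  r0 <- rbind(mk("A", c(1, 2, 3, 4, 5)), mk("B", c(1, 2, 3, 4, 5)))
  out0 <- pairedBonferroni(r0, "rmse", "A")
  expect_equal(out0$t, 0); expect_equal(out0$p, 1)
  ## constant nonzero difference: zero variance is signalled
  r1 <- rbind(mk("A", c(1, 2, 3, 4, 5)), mk("B", c(1.1, 2.1, 3.1, 4.1, 5.1)))
  expect_warning(out1 <- pairedBonferroni(r1, "rmse", "A"), "zero variance")
  expect_true(is.na(out1$t))
  ## five-pair hand example, two competitors (Bonferroni factor 2)
  a <- c(0.9, 1.1, 1.0, 0.8, 1.2); b <- c(1.0, 1.3, 1.1, 1.0, 1.2)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  pHand <- 2 * pt(-abs(tHand), df = 4)
  r2 <- rbind(mk("A", a), mk("B", b), mk("C", rev(a)))
  out2 <- pairedBonferroni(r2, "rmse", "A")
  rowB <- out2[out2$competitor == "B", ]
  expect_equal(rowB$t, tHand, tolerance = 1e-12)
  expect_equal(rowB$p, pHand, tolerance = 1e-12)
  expect_equal(rowB$pAdjusted, min(1, pHand * 2), tolerance = 1e-12)
})
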