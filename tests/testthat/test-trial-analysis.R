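test_that("daily means equal a group-and-average recomputation", {
  one <- data.frame(user = "a", arm = "COMPARISON", day = rep(1:30, 1), rating = 4)
  s <- dailyMeans(one)
  expect_equal(s$mean, rep(4, 30)); expect_equal(s$n, rep(1L, 30))
  two <- rbind(data.frame(user = "a", day = 1:30, rating = 4),
               data.frame(user = "b", day = 1:30, rating = 2))
  expect_equal(dailyMeans(two)$mean, rep(3, 30))
  set.seed(8)
  logs <- data.frame(user = sample(letters[1:6], 150, TRUE),
                     day = sample(1:30, 150, TRUE),
                     rating = sample(1:5, 150, TRUE))
  s3 <- dailyMeans(logs)
  for (d in 1:30) {
    r <- logs$rating[logs$day == d]
    if (length(r)) expect_equal(s3$mean[d], mean(r)) else expect_true(is.na(s3$mean[d]))
    expect_equal(s3$n[d], length(r))
  }
  expect_error(dailyMeans(logs[0, ]), "no ratings")
})

test_that("the agreement threshold is inclusive and monotone", {
  s4 <- data.frame(day = 1:30, mean = rep(4.0, 30), n = 2L)
  expect_equal(daysAgreed(s4)[c("count", "total")], list(count = 30L, total = 30L))
  s399 <- data.frame(day = 1:30, mean = rep(3.99, 30), n = 2L)
  expect_equal(daysAgreed(s399)$count, 0L)
  s <- data.frame(day = 1:30, mean = seq(3, 5, length.out = 30), n = 1L)
  p <- vapply(c(3, 3.5, 4, 4.5), function(th) daysAgreed(s, th)$proportion, numeric(1))
  expect_true(all(diff(p) <= 0))
  ## a 23-of-30 series reports as the familiar percentage
  s23 <- data.frame(day = 1:30, mean = c(rep(4.2, 23), rep(3.8, 7)), n = 5L)
  da <- daysAgreed(s23)
  expect_equal(da$count, 23L)
  expect_equal(round(da$proportion, 3), 0.767)
})

test_that("the 2x2 chi-square matches an expected-count loop to 1e-10", {
  expect_equal(chi2x2(matrix(c(10, 10, 10, 10), 2, 2))$statistic, 0)
  expect_equal(chi2x2(matrix(c(10, 10, 10, 10), 2, 2))$p, 1)
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    got <- chi2x2(tab)
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- 0
    for (r in 1:2) for (c in 1:2) stat <- stat + (tab[r, c] - exp_[r, c])^2 / exp_[r, c]
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-10)
    ## invariance to transposition and to swapping both labels
    expect_equal(chi2x2(t(tab))$statistic, stat, tolerance = 1e-10)
    expect_equal(chi2x2(tab[2:1, 2:1])$statistic, stat, tolerance = 1e-10)
  }
  expect_error(chi2x2(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
  expect_error(chi2x2(matrix(1:6, 2, 3)), "2x2")
})

test_that("window t tests follow the pooled-variance formula", {
  sA <- data.frame(day = 1:30, mean = rep(4, 30), n = 1L)
  idA <- windowTTest(sA, sA, c(1, 12))
  expect_equal(idA$t, 0); expect_equal(idA$p, 1)
  sB <- data.frame(day = 1:30, mean = rep(3, 30), n = 1L)
  sep <- windowTTest(sA, sB, c(1, 30))
  expect_gt(sep$t, 0); expect_lt(sep$p, 1e-10)
  ## 5-day toy window against the textbook computation
  a <- c(4.1, 4.3, 3.9, 4.2, 4.0); b <- c(3.8, 4.0, 3.7, 3.9, 3.6)
  s1 <- data.frame(day = 1:5, mean = a, n = 1L)
  s2 <- data.frame(day = 1:5, mean = b, n = 1L)
  got <- windowTTest(s1, s2, c(1, 5))
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tHand), 8), tolerance = 1e-12)
  expect_equal(got$seA, sd(a) / sqrt(5))
  expect_error(windowTTest(s1, s2, c(1, 9)), "window")
})

test_that("influence dichotomization conserves completers", {
  resp <- c(5, 5, 5, 4); arm <- c("COMPARISON", "INTERVENTION", "INTERVENTION",
                                  "COMPARISON")
  tab <- dichotomizeInfluence(resp, arm)
  expect_equal(unname(tab["agree", ]), c(2L, 2L))
  expect_equal(unname(tab["disagree_neutral", ]), c(0L, 0L))
  set.seed(10)
  resp2 <- sample(1:5, 40, TRUE); arm2 <- sample(c("COMPARISON", "INTERVENTION"), 40, TRUE)
  tab2 <- dichotomizeInfluence(resp2, arm2)
  expect_equal(sum(tab2), 40L)
  expect_equal(unname(colSums(tab2)), unname(as.integer(table(factor(arm2,
    levels = c("COMPARISON", "INTERVENTION"))))))
  expect_error(dichotomizeInfluence(c(0, 3), c("COMPARISON", "COMPARISON")), "1..5")
})

test_that("ladder movement is strict ascent on the five-level ordering", {
  lm <- ladderMovement(c("THINKING", "ALREADY_QUIT", "SET_QUIT_DATE"),
                       c("SET_QUIT_DATE", "ALREADY_QUIT", "THINKING"),
                       c("INTERVENTION", "COMPARISON", "COMPARISON"))
  expect_equal(lm$movedUp, c(TRUE, FALSE, FALSE))
  expect_equal(sum(lm$table), 3L)
  expect_error(ladderMovement("THINKING", c("THINKING", "THINKING"), "X"), "paired")
})
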