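## Statistical analysis of the two-arm messaging trial: daily mean ratings,
## days-agreed proportions, 2x2 chi-square tests, windowed t tests,
## dichotomized influence tables, and readiness-ladder movement.

#' Daily mean rating series for one arm
#'
#' The daily rating of day d is the arithmetic mean of the ratings provided
#' by all users in the group at message ordinal d ("day" is the message
#' ordinal, not calendar time).
#'
#' @param logs \code{data.frame} of session-log rows for one arm, with columns
#'   \code{day} and \code{rating} (and anything else, ignored).
#' @param nDays Series length (default 30); days with no rater carry NA means
#'   and n = 0.
#' @return \code{data.frame} with columns day, mean, n.
#' @export
dailyMeans <- function(logs, nDays = 30) {
  if (!nrow(logs)) stop("no ratings to average", call. = FALSE)
  stopifnot(all(c("day", "rating") %in% names(logs)))
  out <- data.frame(day = seq_len(nDays), mean = NA_real_, n = 0L)
  agg <- tapply(logs$rating, factor(logs$day, levels = seq_len(nDays)), mean)
  cnt <- tapply(logs$rating, factor(logs$day, levels = seq_len(nDays)), length)
  out$mean <- as.numeric(agg)
  out$n <- as.integer(ifelse(is.na(cnt), 0L, cnt))
  out
}

#' Days on which an arm's daily rating reached the agreement threshold
#'
#' @param series A daily-mean series from [dailyMeans()].
#' @param threshold Agreement cut point (default 4: "agree"/"strongly agree").
#' @return List with \code{count} (days with mean >= threshold), \code{total}
#'   (days with a defined mean) and \code{proportion}.
#' @export
daysAgreed <- function(series, threshold = 4) {
  stopifnot(is.data.frame(series), "mean" %in% names(series))
  ok <- !is.na(series$mean)
  if (!any(ok)) stop("series has no defined days", call. = FALSE)
  count <- sum(series$mean[ok] >= threshold)
  list(count = count, total = sum(ok), proportion = count / sum(ok))
}

#' Pearson chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with df = 1 and no continuity correction, the test used
#' for all dichotomized trial comparisons.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return List with \code{statistic}, \code{p}, \code{expected}.
#' @examples
#' chi2x2(matrix(c(23, 14, 7, 16), 2, 2))  # days agreed, 30 days per arm
#' @export
chi2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be nonnegative with positive total",
                                          call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts undefined", call. = FALSE)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))  # asymptotic test by design
  list(statistic = unname(ht$statistic), p = ht$p.value, expected = ht$expected)
}

#' Two-sample t test of daily mean ratings over a day window
#'
#' Student (pooled-variance) two-sample t test of the per-day means of two
#' arms within a window of message days; days on which either arm has no
#' defined mean are excluded pairwise, and the effective n is reported. Each
#' arm's summary is the mean of its daily-mean series and the standard error
#' of that series over the window.
#'
#' @param seriesA,seriesB Daily-mean series from [dailyMeans()] (A is
#'   conventionally the intervention arm).
#' @param window Length-2 integer day range, within 1..nrow(series).
#' @return List with meanA, seA, meanB, seB, t, df, p, nDays.
#' @export
windowTTest <- function(seriesA, seriesB, window = c(1, 12)) {
  if (length(window) != 2L || window[1] < 1 || window[2] > nrow(seriesA) ||
      window[2] > nrow(seriesB) || window[1] > window[2])
    stop("window outside the day range of the series", call. = FALSE)
  days <- seq(window[1], window[2])
  a <- seriesA$mean[days]; b <- seriesB$mean[days]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("window has fewer than two jointly defined days", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    ## both series constant: zero pooled variance, the t statistic degenerates
    tv <- if (a[1] == b[1]) 0 else Inf * sign(a[1] - b[1])
    return(list(meanA = mean(a), seA = 0, meanB = mean(b), seB = 0,
                t = tv, df = 2 * length(a) - 2,
                p = if (a[1] == b[1]) 1 else 0, nDays = length(a)))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(meanA = mean(a), seA = sd(a) / sqrt(length(a)),
       meanB = mean(b), seB = sd(b) / sqrt(length(b)),
       t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       nDays = length(a))
}

#' Dichotomize 5-level influence responses into a 2x2 table by arm
#'
#' Rows are response categories (1-3: strongly disagree/disagree/neutral;
#' 4-5: agree/strongly agree), columns the trial arms.
#'
#' @param responses Integer vector of responses coded 1..5 (NAs dropped).
#' @param arm Parallel character vector, \code{"COMPARISON"} or
#'   \code{"INTERVENTION"}.
#' @return 2x2 integer matrix with dimnames.
#' @export
dichotomizeInfluence <- function(responses, arm) {
  ok <- !is.na(responses)
  responses <- responses[ok]; arm <- arm[ok]
  if (any(!responses %in% 1:5))
    stop("responses must be coded 1..5", call. = FALSE)
  if (any(!arm %in% c("COMPARISON", "INTERVENTION")))
    stop("arm must be COMPARISON or INTERVENTION", call. = FALSE)
  row <- factor(ifelse(responses >= 4, "agree", "disagree_neutral"),
                levels = c("disagree_neutral", "agree"))
  tab <- table(row, factor(arm, levels = c("COMPARISON", "INTERVENTION")))
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}

#' Readiness-ladder movement between baseline and follow-up
#'
#' A participant moved up the ladder when the follow-up stage is strictly
#' higher than the baseline stage under the five-level ordering.
#'
#' @param baseline,followup Parallel stage vectors (see [readinessStages()]);
#'   pairs with a missing follow-up are dropped.
#' @param arm Parallel arm labels.
#' @return List with \code{movedUp} (logical per analyzed pair) and
#'   \code{table} (2x2 counts: arms x moved/not).
#' @export
ladderMovement <- function(baseline, followup, arm) {
  if (length(baseline) != length(followup) || length(baseline) != length(arm))
    stop("baseline, followup and arm must be paired", call. = FALSE)
  ok <- !is.na(followup) & !is.na(baseline)
  moved <- stageIndex(followup[ok]) > stageIndex(baseline[ok])
  tab <- table(factor(arm[ok], levels = c("INTERVENTION", "COMPARISON")),
               factor(ifelse(moved, "moved_up", "did_not"),
                      levels = c("moved_up", "did_not")))
  list(movedUp = moved, table = matrix(as.integer(tab), 2, 2,
                                       dimnames = dimnames(tab)))
}

#' Published outcome tables of the PERSPeCT randomized messaging pilot
#'
#' The 2x2 contingency tables reported by the 120-smoker randomized pilot of
#' the PERSPeCT recommender against the standard rule-based comparator:
#' days-agreed counts (days with mean daily rating >= 4, out of 30 per arm),
#' the dichotomized perceived-influence responses for quitting smoking and
#' nicotine-replacement use among follow-up completers, one-day quit counts,
#' and readiness-ladder movement. Supplied as reference inputs for the
#' contingency analyses.
#'
#' @return Named list of 2x2 integer matrices with dimnames.
#' @examples
#' round(chi2x2(trialContingencyTables()$days_agreed)$p, 2)  # 0.02
#' @export
trialContingencyTables <- function() {
  list(
    days_agreed = matrix(c(23, 14, 7, 16), 2, 2,
                         dimnames = list(c("INTERVENTION", "COMPARISON"),
                                         c("agreed", "not_agreed"))),
    quit_smoking_influence = matrix(c(14, 23, 12, 46), 2, 2,
                                    dimnames = list(c("disagree_neutral", "agree"),
                                                    c("COMPARISON", "INTERVENTION"))),
    nrt_influence = matrix(c(20, 17, 21, 37), 2, 2,
                           dimnames = list(c("disagree_neutral", "agree"),
                                           c("COMPARISON", "INTERVENTION"))),
    one_day_quit = matrix(c(20, 11, 35, 23), 2, 2,
                          dimnames = list(c("INTERVENTION", "COMPARISON"),
                                          c("quit", "did_not"))),
    ladder_movement = matrix(c(26, 14, 48, 32), 2, 2,
                             dimnames = list(c("INTERVENTION", "COMPARISON"),
                                             c("moved_up", "did_not"))))
}

#' Full statistical analysis of a two-arm messaging trial
#'
#' Computes, per arm, the daily mean rating series and days-agreed
#' proportion; the days-agreed 2x2 chi-square comparison; windowed t tests of
#' the daily means; and, from follow-up outcomes, the one-day-quit
#' chi-square, readiness-ladder movement chi-square, and a dichotomized
#' chi-square per influence question.
#'
#' @param logs Session logs with columns user, arm, day, rating.
#' @param followup Follow-up outcomes from [simulateFollowup()] (or a real
#'   equivalent); \code{NULL} skips the follow-up analyses.
#' @param threshold Days-agreed cut point (default 4).
#' @param windows List of day windows for t tests (default days 1-12 and
#'   13-30, the early and late delivery periods).
#' @param nDays Series length (default 30).
#' @param questions Influence-question columns of \code{followup} to analyze.
#' @return A list of class \code{"trialAnalysis"}.
#' @export
analyzeTrial <- function(logs, followup = NULL, threshold = 4,
                         windows = list(c(1, 12), c(13, 30)), nDays = 30,
                         questions = c("quit_smoking", "use_nrt")) {
  stopifnot(all(c("arm", "day", "rating") %in% names(logs)))
  sInt <- dailyMeans(logs[logs$arm == "INTERVENTION", ], nDays)
  sCmp <- dailyMeans(logs[logs$arm == "COMPARISON", ], nDays)
  daInt <- daysAgreed(sInt, threshold)
  daCmp <- daysAgreed(sCmp, threshold)
  daTab <- matrix(c(daInt$count, daCmp$count,
                    daInt$total - daInt$count, daCmp$total - daCmp$count), 2, 2,
                  dimnames = list(c("INTERVENTION", "COMPARISON"),
                                  c("agreed", "not_agreed")))
  out <- list(
    dailySeries = list(INTERVENTION = sInt, COMPARISON = sCmp),
    daysAgreed = list(INTERVENTION = daInt, COMPARISON = daCmp,
                      table = daTab, test = chi2x2(daTab)),
    windowTests = lapply(windows, function(w)
      c(list(window = w), windowTTest(sInt, sCmp, w))))
  if (!is.null(followup)) {
    comp <- followup[followup$completed, , drop = FALSE]
    quitTab <- table(factor(comp$arm, levels = c("INTERVENTION", "COMPARISON")),
                     factor(ifelse(comp$quitOneDay, "quit", "did_not"),
                            levels = c("quit", "did_not")))
    quitTab <- matrix(as.integer(quitTab), 2, 2, dimnames = dimnames(quitTab))
    lm <- ladderMovement(comp$baselineStage, comp$followupStage, comp$arm)
    out$quit <- list(table = quitTab, test = tryCatch(chi2x2(quitTab),
                                                      error = function(e) NULL))
    out$ladder <- list(table = lm$table, test = tryCatch(chi2x2(lm$table),
                                                         error = function(e) NULL))
    out$influence <- lapply(setNames(questions, questions), function(q) {
      tab <- dichotomizeInfluence(comp[[q]], comp$arm)
      list(table = tab, test = tryCatch(chi2x2(tab), error = function(e) NULL))
    })
    out$completers <- nrow(comp)
  }
  class(out) <- "trialAnalysis"
  out
}

#' @export
print.trialAnalysis <- function(x, ...) {
  fmtPct <- function(p) sprintf("%d%%", roundHalfUp(100 * p))
  di <- x$daysAgreed$INTERVENTION; dc <- x$daysAgreed$COMPARISON
  cat("Two-arm messaging trial analysis\n")
  cat(sprintf("  days agreed (daily mean >= threshold): intervention %s (%d/%d), comparison %s (%d/%d), P=%.2f\n",
              fmtPct(di$proportion), di$count, di$total,
              fmtPct(dc$proportion), dc$count, dc$total, x$daysAgreed$test$p))
  for (wt in x$windowTests)
    cat(sprintf("  days %d-%d: intervention mean %.2f (SE %.2f) vs comparison %.2f (SE %.2f), P=%.3f\n",
                wt$window[1], wt$window[2], wt$meanA, wt$seA, wt$meanB, wt$seB, wt$p))
  if (!is.null(x$quit) && !is.null(x$quit$test))
    cat(sprintf("  one-day quit: P=%.2f\n", x$quit$test$p))
  if (!is.null(x$ladder) && !is.null(x$ladder$test))
    cat(sprintf("  moved up readiness ladder: P=%.2f\n", x$ladder$test$p))
  for (q in names(x$influence))
    if (!is.null(x$influence[[q]]$test))
      cat(sprintf("  influence (%s): P=%.2f\n", q, x$influence[[q]]$test$p))
  invisible(x)
}
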