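## Strong-generalization algorithm bake-off: test users are entirely held out
## of training; only a budget of their own observed ratings informs
## user-specific parameters at evaluation time.

#' Configuration for the strong-generalization protocol
#'
#' @param nUserFolds Number of user folds (default 5).
#' @param nRepeats Random train/validation repeats per test fold (default 3).
#' @param ratingFoldsPerUser Rating folds per test user (default 5).
#' @param observedSizes Observed-rating budgets for cold-start inference
#'   (default \code{c(5, 10, 16)}).
#' @param testPerFold Held-out test ratings per rating fold (default 4).
#' @param validationFraction Fraction of train users held out per repeat for
#'   hyperparameter selection (default 0.2).
#' @param seed Integer seed controlling every split.
#' @return A validated list of class \code{"protocolConfig"}.
#' @export
protocolConfig <- function(nUserFolds = 5, nRepeats = 3, ratingFoldsPerUser = 5,
                           observedSizes = c(5, 10, 16), testPerFold = 4,
                           validationFraction = 0.2, seed = 1) {
  assertCount(nUserFolds, "nUserFolds"); assertCount(nRepeats, "nRepeats")
  assertCount(ratingFoldsPerUser, "ratingFoldsPerUser")
  assertCount(testPerFold, "testPerFold")
  if (!length(observedSizes) || any(observedSizes < 1))
    stop("observedSizes must be positive counts", call. = FALSE)
  structure(list(nUserFolds = as.integer(nUserFolds),
                 nRepeats = as.integer(nRepeats),
                 ratingFoldsPerUser = as.integer(ratingFoldsPerUser),
                 observedSizes = as.integer(sort(observedSizes)),
                 testPerFold = as.integer(testPerFold),
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "protocolConfig")
}

#' Partition users into folds
#'
#' Random balanced partition: fold sizes differ by at most one (larger folds
#' first), deterministic per seed. 846 users in 5 folds gives sizes
#' 170, 169, 169, 169, 169.
#'
#' @param users Character vector of user ids.
#' @param nFolds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..nFolds), named by user.
#' @export
splitUsers <- function(users, nFolds = 5, seed = 1) {
  assertCount(nFolds, "nFolds")
  n <- length(users)
  if (n < nFolds) stop("need at least as many users as folds", call. = FALSE)
  sizes <- rep(n %/% nFolds, nFolds)
  extra <- n %% nFolds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  withSeed(seed, {
    perm <- sample(n)
    fold <- integer(n)
    fold[perm] <- rep(seq_len(nFolds), times = sizes)
    names(fold) <- users
    fold
  })
}

#' Split one test user's ratings into test folds and observed budgets
#'
#' Partitions the user's ratings into \code{ratingFoldsPerUser} folds of
#' exactly \code{testPerFold} test ratings each; for every fold, observed
#' subsets of each budget size are drawn from the remaining ratings (nested,
#' so a budget equal to the full remainder is exactly the complement of the
#' test fold). Observed and test sets are disjoint by construction.
#'
#' @param n Number of ratings the user has.
#' @param config A [protocolConfig()].
#' @param seed Integer seed.
#' @param user Optional user id used in error messages.
#' @return A list with one element per rating fold, each
#'   \code{list(test = <indices>, observed = <named list of index vectors>)}.
#' @export
splitUserRatings <- function(n, config = protocolConfig(), seed = 1, user = "?") {
  k <- config$ratingFoldsPerUser * config$testPerFold
  if (n < k)
    stop(sprintf("user %s has %d ratings; the protocol needs at least %d",
                 user, n, k), call. = FALSE)
  if (max(config$observedSizes) > n - config$testPerFold)
    stop(sprintf("user %s: observed budget %d exceeds the %d ratings left after the test fold",
                 user, max(config$observedSizes), n - config$testPerFold),
         call. = FALSE)
  withSeed(seed, {
    perm <- sample(n)
    lapply(seq_len(config$ratingFoldsPerUser), function(f) {
      test <- perm[(f - 1L) * config$testPerFold + seq_len(config$testPerFold)]
      remaining <- sample(setdiff(seq_len(n), test))
      observed <- lapply(config$observedSizes, function(s) sort(remaining[seq_len(s)]))
      names(observed) <- as.character(config$observedSizes)
      list(test = sort(test), observed = observed)
    })
  })
}

## ---------------------------------------------------------------------------
## Algorithm adaptors
##
## An algorithm is a list with fields
##   name       : label used in reports,
##   fit        : function(trainData, seed) -> model,
##   predictNew : function(model, user, obsMessages, obsRatings, targets)
##                -> numeric predictions for `targets`.
## Messages absent from the training index are predicted at the training mean.

#' Protocol adaptor for the BPMF model
#'
#' @param ... Arguments passed to [fitBPMF()] (e.g. \code{latentDim},
#'   \code{alpha}, \code{nSamples}, \code{burnIn}).
#' @param name Report label.
#' @return An algorithm adaptor for [runProtocol()].
#' @export
algoBPMF <- function(..., name = "BPMF") {
  args <- list(...)
  list(name = name,
       fit = function(train, seed) do.call(fitBPMF, c(list(data = train, seed = seed), args)),
       predictNew = function(model, user, obsMessages, obsRatings, targets) {
         known <- obsMessages %in% messageIds(model)
         uf <- inferNewUser(model, obsMessages[known], obsRatings[known])
         out <- rep(clipRating(model@offset), length(targets))
         tk <- targets %in% messageIds(model)
         if (any(tk)) out[tk] <- predictNewUser(model, uf, targets[tk])
         out
       })
}

#' Protocol adaptor for MAP probabilistic matrix factorization
#'
#' @param ... Arguments passed to [fitPMF()].
#' @param name Report label.
#' @return An algorithm adaptor for [runProtocol()].
#' @export
algoPMF <- function(..., name = "PMF") {
  args <- list(...)
  list(name = name,
       fit = function(train, seed) do.call(fitPMF, c(list(data = train, seed = seed), args)),
       predictNew = function(model, user, obsMessages, obsRatings, targets) {
         known <- obsMessages %in% messageIds(model)
         uf <- inferNewUser(model, obsMessages[known], obsRatings[known])
         out <- rep(clipRating(model@offset), length(targets))
         tk <- targets %in% messageIds(model)
         if (any(tk)) out[tk] <- predictNewUser(model, uf, targets[tk])
         out
       })
}

#' Protocol adaptor for user-based K-NN
#'
#' @param k,minOverlap See [knnPredict()].
#' @param name Report label.
#' @return An algorithm adaptor for [runProtocol()].
#' @export
algoKNN <- function(k = 20, minOverlap = 3, name = "KNN") {
  list(name = name,
       fit = function(train, seed) train,
       predictNew = function(model, user, obsMessages, obsRatings, targets) {
         known <- obsMessages %in% messageIds(model)
         tk <- targets %in% messageIds(model)
         out <- rep(mean(ratingTriplets(model)$rating), length(targets))
         if (any(tk))
           out[tk] <- knnPredictNew(model, obsMessages[known], obsRatings[known],
                                    targets[tk], k = k, minOverlap = minOverlap)
         out
       })
}

#' Protocol adaptor for mean baselines
#'
#' @param mode See [baselinePredict()]. \code{USER_MEAN} uses the mean of the
#'   new user's observed ratings.
#' @param name Report label (defaults to the mode).
#' @return An algorithm adaptor for [runProtocol()].
#' @export
algoBaseline <- function(mode = "GLOBAL_MEAN", name = mode) {
  force(name)
  list(name = name,
       fit = function(train, seed) train,
       predictNew = function(model, user, obsMessages, obsRatings, targets) {
         g <- mean(ratingTriplets(model)$rating)
         if (mode == "GLOBAL_MEAN") return(rep(g, length(targets)))
         if (mode == "USER_MEAN") {
           m <- if (length(obsRatings)) mean(obsRatings) else g
           return(rep(m, length(targets)))
         }
         baselinePredict(model, "MESSAGE_MEAN", message = targets)
       })
}

## ---------------------------------------------------------------------------

#' Exhaustive grid search with boundary extension
#'
#' Evaluates every combination of the hyperparameter grid by validation RMSE
#' (strong-generalization on the validation users: all but \code{testPerFold}
#' of each validation user's ratings are observed, the rest scored). If any
#' selected value sits at an endpoint of its range, the range is extended one
#' step in that direction and the search repeats, up to
#' \code{maxExtensions} times; if the cap is reached with a boundary still
#' selected, a warning is recorded on the result.
#'
#' @param makeAlgo Function taking a named list of hyperparameter values and
#'   returning an algorithm adaptor (see [algoBPMF()]).
#' @param grid Named list of sorted numeric candidate vectors.
#' @param train,validation [RatingDataset-class] objects with disjoint users.
#' @param testPerFold Held-out ratings per validation user (default 4).
#' @param seed Integer seed.
#' @param maxExtensions Extension cap per direction (default 3).
#' @return List with \code{params} (named list of selected values),
#'   \code{rmse}, \code{nExtensions}, and \code{boundary} (TRUE if the cap was
#'   hit with an endpoint still selected).
#' @export
gridSearch <- function(makeAlgo, grid, train, validation, testPerFold = 4,
                       seed = 1, maxExtensions = 3) {
  if (!length(grid) || any(!vapply(grid, length, 1L)))
    stop("each hyperparameter needs a nonempty candidate vector", call. = FALSE)
  grid <- lapply(grid, sort)
  valTrip <- ratingTriplets(validation)
  valUsers <- userIds(validation)

  evalParams <- function(params) {
    alg <- makeAlgo(params)
    model <- alg$fit(train, seed)
    pr <- c(); ac <- c()
    for (u in valUsers) {
      tri <- valTrip[valTrip$user == u, , drop = FALSE]
      if (nrow(tri) <= testPerFold) next
      idx <- withSeed(seed + match(u, valUsers), sample(nrow(tri)))
      test <- idx[seq_len(testPerFold)]
      obs <- idx[-seq_len(testPerFold)]
      pr <- c(pr, alg$predictNew(model, u, tri$message[obs], tri$rating[obs],
                                 tri$message[test]))
      ac <- c(ac, tri$rating[test])
    }
    rmse(pr, ac)
  }

  nExt <- 0L
  repeat {
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    scores <- vapply(seq_len(nrow(combos)), function(i)
      evalParams(as.list(combos[i, , drop = FALSE])), numeric(1))
    best <- which.min(scores)           # ties -> first (lowest) combination
    sel <- as.list(combos[best, , drop = FALSE])
    atEnd <- vapply(names(grid), function(p) {
      g <- grid[[p]]
      length(g) > 1L && (sel[[p]] == g[1] || sel[[p]] == g[length(g)])
    }, logical(1))
    if (!any(atEnd) || nExt >= maxExtensions) break
    for (p in names(grid)[atEnd]) {
      g <- grid[[p]]
      step <- min(diff(g))
      if (sel[[p]] == g[1] && g[1] - step > 0) grid[[p]] <- c(g[1] - step, g)
      if (sel[[p]] == g[length(g)]) grid[[p]] <- c(g, g[length(g)] + step)
    }
    nExt <- nExt + 1L
  }
  boundary <- any(atEnd)
  if (boundary)
    warning("grid-search extension cap reached with a boundary value still selected")
  list(params = sel, rmse = scores[best], nExtensions = nExt, boundary = boundary)
}

#' Run the strong-generalization protocol
#'
#' For each user fold: every algorithm is trained on all train users' ratings
#' (per repeat, with a repeat-specific seed); for each test user, the user's
#' ratings are split into rating folds, user-specific parameters are inferred
#' from observed subsets of each budget size, and the held-out test ratings
#' are scored. Results are aggregated into one report row per
#' (algorithm, user fold, repeat, observed size): pooled RMSE, and mean
#' per-user-fold Kendall tau-b and NDCG over the test lists (undefined
#' values, e.g. from fully tied test ratings, are dropped from the mean).
#'
#' @param algorithms Named or unnamed list of algorithm adaptors
#'   ([algoBPMF()], [algoPMF()], [algoKNN()], [algoBaseline()], or any list
#'   providing \code{name}, \code{fit}, \code{predictNew}).
#' @param data A [RatingDataset-class] whose every user satisfies the
#'   protocol's per-user minimum ratings.
#' @param config A [protocolConfig()].
#' @return A \code{data.frame} of class \code{"EvalReport"} with columns
#'   algorithm, fold, rep, observedSize, rmse, kendallTauB, ndcg, n (number of
#'   scored ratings), nUsers; the protocol configuration is attached as
#'   attribute \code{"config"}.
#' @export
runProtocol <- function(algorithms, data, config = protocolConfig()) {
  stopifnot(is(data, "RatingDataset"))
  if (!length(algorithms)) stop("need at least one algorithm", call. = FALSE)
  trip <- ratingTriplets(data)
  fold <- splitUsers(userIds(data), config$nUserFolds, config$seed)
  perUser <- split(seq_len(nrow(trip)), trip$user)
  rows <- list()
  for (f in seq_len(config$nUserFolds)) {
    testUsers <- names(fold)[fold == f]
    trainUsers <- names(fold)[fold != f]
    trainTrip <- trip[trip$user %in% trainUsers, , drop = FALSE]
    trainData <- RatingDataset(trainTrip, userIds = trainUsers,
                               messageIds = unique(trainTrip$message))
    ## pre-compute each test user's rating folds (shared across repeats)
    userFolds <- lapply(testUsers, function(u) {
      idx <- perUser[[u]]
      splitUserRatings(length(idx), config,
                       seed = config$seed + 7919L + match(u, names(fold)),
                       user = u)
    })
    names(userFolds) <- testUsers
    for (rp in seq_len(config$nRepeats)) {
      repSeed <- config$seed + 1009L * f + 97L * rp
      for (alg in algorithms) {
        model <- tryCatch(alg$fit(trainData, repSeed),
                          error = function(e)
                            stop(sprintf("algorithm %s failed to fit in fold %d repeat %d: %s",
                                         alg$name, f, rep, conditionMessage(e)),
                                 call. = FALSE))
        for (s in config$observedSizes) {
          errs <- c(); taus <- c(); ndcgs <- c(); nu <- 0L
          for (u in testUsers) {
            idx <- perUser[[u]]
            nu <- nu + 1L
            for (rf in userFolds[[u]]) {
              obs <- idx[rf$observed[[as.character(s)]]]
              tst <- idx[rf$test]
              pred <- alg$predictNew(model, u, trip$message[obs],
                                     trip$rating[obs], trip$message[tst])
              act <- trip$rating[tst]
              errs <- c(errs, pred - act)
              taus <- c(taus, suppressWarnings(kendallTauB(pred, act)))
              ndcgs <- c(ndcgs, suppressWarnings(ndcg(pred, act)))
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            algorithm = alg$name, fold = f, rep = rp, observedSize = s,
            rmse = sqrt(mean(errs^2)),
            kendallTauB = mean(taus, na.rm = TRUE),
            ndcg = mean(ndcgs, na.rm = TRUE),
            n = length(errs), nUsers = nu, stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("EvalReport", "data.frame")
  attr(report, "config") <- config
  report
}

#' Paired t comparisons of a reference algorithm against competitors
#'
#' Two-sided paired t tests of the reference algorithm's metric against each
#' competitor over matched protocol cells (fold x repeat x observed size),
#' with Bonferroni adjustment over the number of competitors. Zero variance
#' of the paired differences leaves the statistic undefined (NA, with a
#' warning).
#'
#' @param report An \code{EvalReport} from [runProtocol()].
#' @param metric One of \code{"rmse"}, \code{"kendallTauB"}, \code{"ndcg"}.
#' @param reference Algorithm name to compare against.
#' @return \code{data.frame} with columns competitor, meanDiff, t, df, p,
#'   pAdjusted.
#' @export
pairedBonferroni <- function(report, metric = "rmse", reference) {
  stopifnot(metric %in% c("rmse", "kendallTauB", "ndcg"))
  algs <- unique(report$algorithm)
  if (!reference %in% algs) stop("reference algorithm not in report", call. = FALSE)
  competitors <- setdiff(algs, reference)
  if (!length(competitors)) stop("no competitors to compare", call. = FALSE)
  key <- function(d) paste(d$fold, d$rep, d$observedSize)
  ref <- report[report$algorithm == reference, ]
  out <- lapply(competitors, function(a) {
    cmp <- report[report$algorithm == a, ]
    m <- match(key(ref), key(cmp))
    x <- ref[[metric]]; y <- cmp[[metric]][m]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2) stop("fewer than two paired cells", call. = FALSE)
    d <- x[ok] - y[ok]
    if (sd(d) <= 1e-12 * max(abs(d), 1)) {
      if (all(d == 0))    # identical metric vectors: no difference at all
        return(data.frame(competitor = a, meanDiff = 0, t = 0,
                          df = length(d) - 1, p = 1, pAdjusted = 1))
      warning(sprintf("zero variance of paired differences for %s; t undefined", a))
      return(data.frame(competitor = a, meanDiff = mean(d), t = NA_real_,
                        df = length(d) - 1, p = NA_real_, pAdjusted = NA_real_))
    }
    tt <- t.test(x[ok], y[ok], paired = TRUE)
    data.frame(competitor = a, meanDiff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               pAdjusted = min(1, tt$p.value * length(competitors)))
  })
  do.call(rbind, out)
}
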