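## Comparator prediction algorithms: MAP probabilistic matrix factorization
## fitted by alternating ridge least squares, user-based K-NN with Pearson
## similarity, and mean baselines.

ridgeSide <- function(idx, counterpart, y, nEnt, lambda) {
  D <- ncol(counterpart)
  st <- factorSuffStats(idx, counterpart, y, nEnt)
  F <- matrix(0, nEnt, D)
  for (i in seq_len(nEnt)) {
    prec <- diag(lambda, D) + matrix(st$S[i, ], D, D)
    F[i, ] <- solve(prec, st$b[i, ])
  }
  F
}

pmfObjective <- function(U, V, ui, mi, y, lambda) {
  resid <- y - rowSums(U[ui, , drop = FALSE] * V[mi, , drop = FALSE])
  sum(resid^2) + lambda * (sum(U^2) + sum(V^2))
}

#' Fit MAP probabilistic matrix factorization by alternating least squares
#'
#' Minimizes the ridge-penalized squared error
#' \eqn{\sum (r - offset - u'v)^2 + \lambda(\|U\|^2 + \|V\|^2)} by exact
#' alternating ridge solves, which makes the objective monotone
#' non-increasing. Iteration stops when the relative objective change falls
#' below \code{tol} or after \code{maxIter} alternations.
#'
#' @param data A [RatingDataset-class]; every indexed user/message needs at
#'   least one rating.
#' @param latentDim Latent dimensionality (default 10).
#' @param lambda Ridge weight (default 1).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @param maxIter Maximum alternations (default 500).
#' @param seed Seed for the random initialization.
#' @return A [PMFFit-class].
#' @export
fitPMF <- function(data, latentDim = 10, lambda = 1, tol = 1e-6,
                   maxIter = 500, seed = 1) {
  stopifnot(is(data, "RatingDataset"))
  D <- assertCount(latentDim, "latentDim")
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  r <- ratingTriplets(data)
  ui <- match(r$user, userIds(data)); mi <- match(r$message, messageIds(data))
  if (!all(tabulate(ui, nUsers(data)) > 0L) ||
      !all(tabulate(mi, nMessages(data)) > 0L))
    stop("every indexed user and message needs at least one rating", call. = FALSE)
  offset <- mean(r$rating)
  y <- r$rating - offset
  nU <- nUsers(data); nM <- nMessages(data)
  withSeed(seed, {
    U <- matrix(rnorm(nU * D, 0, 0.1), nU, D)
    V <- matrix(rnorm(nM * D, 0, 0.1), nM, D)
    obj <- pmfObjective(U, V, ui, mi, y, lambda)
    for (it in seq_len(maxIter)) {
      U <- ridgeSide(ui, V[mi, , drop = FALSE], y, nU, lambda)
      V <- ridgeSide(mi, U[ui, , drop = FALSE], y, nM, lambda)
      obj <- c(obj, pmfObjective(U, V, ui, mi, y, lambda))
      n <- length(obj)
      if (abs(obj[n - 1] - obj[n]) <= tol * max(1, abs(obj[n - 1]))) break
    }
    new("PMFFit", userFactors = U, itemFactors = V, offset = offset,
        lambda = lambda, objective = obj,
        userIds = userIds(data), messageIds = messageIds(data),
        config = list(latentDim = D, lambda = lambda, tol = tol,
                      maxIter = as.integer(maxIter), seed = as.integer(seed)))
  })
}

setMethod("show", "PMFFit", function(object) {
  cat(sprintf("PMFFit: %d users x %d messages, D=%d, lambda=%g, %d alternations\n",
              nrow(object@userFactors), nrow(object@itemFactors),
              ncol(object@userFactors), object@lambda,
              length(object@objective) - 1L))
})

#' @describeIn PMFFit-class user index
#' @param x A PMFFit.
#' @export
setMethod("userIds", "PMFFit", function(x) x@userIds)

#' @describeIn PMFFit-class message index
#' @export
setMethod("messageIds", "PMFFit", function(x) x@messageIds)

#' @rdname predictRating
#' @export
setMethod("predictRating", "PMFFit", function(model, user, message) {
  n <- max(length(user), length(message))
  uidx <- match(rep_len(as.character(user), n), model@userIds)
  midx <- match(rep_len(as.character(message), n), model@messageIds)
  if (anyNA(uidx) || anyNA(midx)) stop("unknown user or message id", call. = FALSE)
  clipRating(rowSums(model@userFactors[uidx, , drop = FALSE] *
                       model@itemFactors[midx, , drop = FALSE]) + model@offset)
})

#' @rdname inferNewUser
#' @export
setMethod("inferNewUser", "PMFFit", function(model, messages, ratings) {
  D <- ncol(model@userFactors)
  if (length(messages) == 0L) return(numeric(D))
  midx <- match(as.character(messages), model@messageIds)
  if (anyNA(midx)) stop("observed message(s) unknown to the model", call. = FALSE)
  Vo <- model@itemFactors[midx, , drop = FALSE]
  y <- as.numeric(ratings) - model@offset
  drop(solve(diag(model@lambda, D) + crossprod(Vo), crossprod(Vo, y)))
})

#' @rdname predictNewUser
#' @export
setMethod("predictNewUser", "PMFFit", function(model, userFactors, message) {
  midx <- match(as.character(message), model@messageIds)
  if (anyNA(midx)) stop("unknown message id(s)", call. = FALSE)
  clipRating(drop(model@itemFactors[midx, , drop = FALSE] %*% userFactors) +
               model@offset)
})

## ---------------------------------------------------------------------------
## User-based K-NN

## Pearson similarity of one rating profile against every row of a sparse
## rating matrix, over co-rated messages only (>= minOverlap).
profileSimilarities <- function(mat, profile, minOverlap) {
  n <- nrow(mat)
  sims <- rep(NA_real_, n)
  pm <- which(profile != 0)
  for (i in seq_len(n)) {
    ri <- mat[i, ]
    common <- intersect(pm, which(ri != 0))
    if (length(common) < max(2L, minOverlap)) next
    s <- suppressWarnings(cor(profile[common], ri[common]))
    if (is.finite(s)) sims[i] <- s
  }
  sims
}

## Shared K-NN core: predict ratings of `targets` for a profile (named,
## possibly partial vector over the message index), given the train matrix.
knnCore <- function(mat, profile, targets, k, minOverlap) {
  sims <- profileSimilarities(mat, profile, minOverlap)
  globalMean <- mean(mat@x)
  profMean <- mean(profile[profile != 0])
  if (!is.finite(profMean)) profMean <- globalMean
  rowMeans <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]; m <- mean(v[v != 0]); if (is.finite(m)) m else globalMean
  }, numeric(1))
  vapply(targets, function(j) {
    raters <- which(mat[, j] != 0)
    cand <- raters[!is.na(sims[raters])]
    if (length(cand)) {
      ## K most similar; ties broken by lower user index for reproducibility
      cand <- cand[order(-sims[cand], cand)]
      top <- head(cand, k)
      w <- sims[top]
      if (sum(abs(w)) > 0) {
        dev <- mat[top, j] - rowMeans[top]
        return(clipRating(profMean + sum(w * dev) / sum(abs(w))))
      }
    }
    if (length(raters)) return(clipRating(mean(mat[raters, j])))
    clipRating(globalMean)
  }, numeric(1))
}

#' User-based K-nearest-neighbour rating prediction
#'
#' Predicts a user's rating of a message as the user's mean rating plus the
#' similarity-weighted average of the K most Pearson-similar users'
#' mean-centred ratings of that message. Similarity is computed over co-rated
#' messages (at least \code{minOverlap}); when no neighbour qualifies the
#' prediction falls back to the message mean, then the global mean.
#'
#' @param data A [RatingDataset-class] (the user must be indexed in it).
#' @param user A user id in `data`.
#' @param message Character vector of target message ids.
#' @param k Neighbourhood size (default 20).
#' @param minOverlap Minimum number of co-rated messages for a similarity to
#'   count (default 3).
#' @return Numeric predictions in [1, 5].
#' @export
knnPredict <- function(data, user, message, k = 20, minOverlap = 3) {
  stopifnot(is(data, "RatingDataset"))
  mat <- ratingMatrix(data)
  uidx <- match(as.character(user), userIds(data))
  if (is.na(uidx)) stop("unknown user id: ", user, call. = FALSE)
  midx <- match(as.character(message), messageIds(data))
  if (anyNA(midx)) stop("unknown message id(s)", call. = FALSE)
  profile <- mat[uidx, ]
  knnCore(mat[-uidx, , drop = FALSE], profile, midx, k, minOverlap)
}

#' @describeIn knnPredict prediction for a user absent from the dataset,
#'   from an observed rating profile (the cold-start analogue).
#' @param observedMessages,observedRatings The new user's observed profile.
#' @export
knnPredictNew <- function(data, observedMessages, observedRatings, message,
                          k = 20, minOverlap = 3) {
  stopifnot(is(data, "RatingDataset"))
  mat <- ratingMatrix(data)
  profile <- numeric(nMessages(data))
  oidx <- match(as.character(observedMessages), messageIds(data))
  if (anyNA(oidx)) stop("observed message(s) not in dataset index", call. = FALSE)
  profile[oidx] <- observedRatings
  midx <- match(as.character(message), messageIds(data))
  if (anyNA(midx)) stop("unknown message id(s)", call. = FALSE)
  knnCore(mat, profile, midx, k, minOverlap)
}

#' Mean-baseline rating prediction
#'
#' The reference floor for algorithm comparisons: the global training mean,
#' the per-message mean, or the per-user mean, with global-mean fallback for
#' empty groups.
#'
#' @param data A [RatingDataset-class].
#' @param mode One of \code{"GLOBAL_MEAN"}, \code{"MESSAGE_MEAN"},
#'   \code{"USER_MEAN"}.
#' @param user,message Ids (required for the respective modes); vectors are
#'   recycled to a common length.
#' @return Numeric predictions.
#' @export
baselinePredict <- function(data, mode = c("GLOBAL_MEAN", "MESSAGE_MEAN", "USER_MEAN"),
                            user = NULL, message = NULL) {
  stopifnot(is(data, "RatingDataset"))
  mode <- match.arg(mode)
  r <- ratingTriplets(data)
  g <- mean(r$rating)
  if (mode == "GLOBAL_MEAN")
    return(rep(g, max(1L, length(user), length(message))))
  if (mode == "MESSAGE_MEAN") {
    if (is.null(message)) stop("MESSAGE_MEAN needs 'message'", call. = FALSE)
    mm <- tapply(r$rating, r$message, mean)
    out <- as.numeric(mm[as.character(message)])
    out[is.na(out)] <- g
    return(out)
  }
  if (is.null(user)) stop("USER_MEAN needs 'user'", call. = FALSE)
  um <- tapply(r$rating, r$user, mean)
  out <- as.numeric(um[as.character(user)])
  out[is.na(out)] <- g
  out
}
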