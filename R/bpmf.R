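## Bayesian probabilistic matrix factorization (the deployed model).
##
## Hierarchical Gaussian factor model of the centred rating matrix:
##   r_um ~ N(u_u' v_m + offset, 1/alpha)
##   u_u ~ N(mu_U, Lambda_U^-1),  v_m ~ N(mu_V, Lambda_V^-1)
##   (mu, Lambda) ~ Normal-Wishart(mu0, beta0, W0, nu0) on each side.
## Inference is by blocked Gibbs sampling; predictions are posterior
## expectations of the factor inner product, clipped to the rating scale.

## Gaussian-Wishart draw for one side's population hyperparameters, given the
## current factor matrix F.
sampleNormalWishart <- function(F, mu0, beta0, nu0, W0inv) {
  N <- nrow(F); D <- ncol(F)
  Fbar <- colMeans(F)
  Sc <- crossprod(sweep(F, 2, Fbar))           # N * sample covariance
  betaStar <- beta0 + N
  nuStar <- nu0 + N
  muStar <- (beta0 * mu0 + N * Fbar) / betaStar
  d <- Fbar - mu0
  WStarInv <- W0inv + Sc + (beta0 * N / betaStar) * tcrossprod(d)
  WStar <- solve((WStarInv + t(WStarInv)) / 2)
  Lambda <- rWishart(1, nuStar, (WStar + t(WStar)) / 2)[, , 1]
  ch <- chol(betaStar * Lambda)
  mu <- drop(muStar + backsolve(ch, rnorm(D)))
  list(mu = mu, Lambda = Lambda)
}

## Conditional Gaussian draw of every factor on one side. S is the per-entity
## rowsum of rated-counterpart outer products (nEnt x D^2), b the rowsum of
## centred-rating-weighted counterpart factors (nEnt x D).
sampleFactorSide <- function(S, b, mu, Lambda, alpha) {
  nEnt <- nrow(b); D <- ncol(b)
  F <- matrix(0, nEnt, D)
  Lmu <- drop(Lambda %*% mu)
  for (i in seq_len(nEnt)) {
    prec <- Lambda + alpha * matrix(S[i, ], D, D)
    ch <- chol(prec)
    m <- backsolve(ch, forwardsolve(t(ch), Lmu + alpha * b[i, ]))
    F[i, ] <- m + backsolve(ch, rnorm(D))
  }
  F
}

## Sufficient statistics for one side: for each entity, the sum of outer
## products of the counterpart factors it rated and the sum of centred
## ratings times counterpart factors. Vectorized via rowsum.
factorSuffStats <- function(idx, counterpart, y, nEnt) {
  D <- ncol(counterpart)
  cp <- counterpart[, rep(seq_len(D), times = D), drop = FALSE] *
    counterpart[, rep(seq_len(D), each = D), drop = FALSE]
  g <- factor(idx, levels = seq_len(nEnt))
  list(S = rowsum(cp, g), b = rowsum(y * counterpart, g))
}

#' Fit a Bayesian probabilistic matrix factorization model by Gibbs sampling
#'
#' Alternates (i) Normal-Wishart draws of the user- and item-population
#' hyperparameters, (ii) conditional Gaussian draws of each user factor given
#' the item factors and that user's ratings, and (iii) the symmetric item
#' update. Ratings are centred by the training mean (the global offset)
#' before factorization; the first \code{burnIn} sweeps are discarded. The
#' sampler is deterministic for a fixed seed.
#'
#' @param data A [RatingDataset-class] in which every indexed user and message
#'   has at least one rating.
#' @param latentDim Latent dimensionality D (default 10).
#' @param alpha Observation noise precision (default 2).
#' @param beta0,nu0,W0,mu0 Normal-Wishart prior: scale \code{beta0} (default
#'   2), degrees of freedom \code{nu0} (default D), scale matrix \code{W0}
#'   (default identity; must be symmetric positive definite), mean \code{mu0}
#'   (default zero).
#' @param nSamples Posterior samples retained (default 200).
#' @param burnIn Discarded initial sweeps (default 50).
#' @param seed Integer seed.
#' @return A [BPMFFit-class].
#' @references Salakhutdinov R, Mnih A (2008). Bayesian probabilistic matrix
#'   factorization using Markov chain Monte Carlo. ICML 25.
#' @examples
#' gen <- generateRatings(generatorConfig(nUsers = 30, nMessages = 20,
#'                                        ratingsPerUser = 8, seed = 3))
#' fit <- fitBPMF(gen$data, latentDim = 2, nSamples = 20, burnIn = 10, seed = 3)
#' predictRating(fit, "u0001", "m001")
#' @export
fitBPMF <- function(data, latentDim = 10, alpha = 2, beta0 = 2,
                    nu0 = latentDim, W0 = diag(latentDim),
                    mu0 = rep(0, latentDim), nSamples = 200, burnIn = 50,
                    seed = 1) {
  stopifnot(is(data, "RatingDataset"))
  D <- assertCount(latentDim, "latentDim")
  assertCount(nSamples, "nSamples"); assertCount(burnIn, "burnIn", min = 0L)
  if (nu0 < D) stop("nu0 must be >= latentDim", call. = FALSE)
  if (!isSymmetric(unname(W0)) || any(eigen(W0, symmetric = TRUE,
                                            only.values = TRUE)$values <= 0))
    stop("W0 must be symmetric positive definite", call. = FALSE)
  r <- ratingTriplets(data)
  ui <- match(r$user, userIds(data))
  mi <- match(r$message, messageIds(data))
  if (!all(tabulate(ui, nUsers(data)) > 0L))
    stop("some indexed users have no ratings; infer them with the cold-start ",
         "path (inferNewUser) instead", call. = FALSE)
  if (!all(tabulate(mi, nMessages(data)) > 0L))
    stop("some indexed messages have no ratings; drop them or use a dataset ",
         "that covers the library", call. = FALSE)
  offset <- mean(r$rating)
  y <- r$rating - offset
  nU <- nUsers(data); nM <- nMessages(data)
  W0inv <- solve(W0)

  withSeed(seed, {
    U <- matrix(rnorm(nU * D, 0, 0.1), nU, D)
    V <- matrix(rnorm(nM * D, 0, 0.1), nM, D)
    keep <- nSamples
    uF <- array(NA_real_, c(keep, nU, D))
    iF <- array(NA_real_, c(keep, nM, D))
    uMu <- matrix(NA_real_, keep, D); iMu <- matrix(NA_real_, keep, D)
    uLam <- array(NA_real_, c(D, D, keep)); iLam <- array(NA_real_, c(D, D, keep))
    for (sweep in seq_len(burnIn + nSamples)) {
      hypU <- sampleNormalWishart(U, mu0, beta0, nu0, W0inv)
      hypV <- sampleNormalWishart(V, mu0, beta0, nu0, W0inv)
      su <- factorSuffStats(ui, V[mi, , drop = FALSE], y, nU)
      U <- sampleFactorSide(su$S, su$b, hypU$mu, hypU$Lambda, alpha)
      sv <- factorSuffStats(mi, U[ui, , drop = FALSE], y, nM)
      V <- sampleFactorSide(sv$S, sv$b, hypV$mu, hypV$Lambda, alpha)
      k <- sweep - burnIn
      if (k >= 1L) {
        uF[k, , ] <- U; iF[k, , ] <- V
        uMu[k, ] <- hypU$mu; iMu[k, ] <- hypV$mu
        uLam[, , k] <- hypU$Lambda; iLam[, , k] <- hypV$Lambda
      }
    }
    new("BPMFFit", userFactors = uF, itemFactors = iF,
        userMu = uMu, itemMu = iMu, userLambda = uLam, itemLambda = iLam,
        offset = offset, alpha = alpha,
        userIds = userIds(data), messageIds = messageIds(data),
        config = list(latentDim = D, alpha = alpha, beta0 = beta0, nu0 = nu0,
                      nSamples = as.integer(nSamples),
                      burnIn = as.integer(burnIn), seed = as.integer(seed)))
  })
}

setMethod("show", "BPMFFit", function(object) {
  d <- dim(object@userFactors)
  cat(sprintf("BPMFFit: %d posterior samples, %d users x %d messages, D=%d\n",
              d[1], d[2], dim(object@itemFactors)[2], d[3]))
  cat(sprintf("  offset=%.3f alpha=%.2f burnIn=%d seed=%d\n", object@offset,
              object@alpha, object@config$burnIn, object@config$seed))
})

#' @describeIn BPMFFit-class user index
#' @param x A BPMFFit.
#' @export
setMethod("userIds", "BPMFFit", function(x) x@userIds)

#' @describeIn BPMFFit-class message index
#' @export
setMethod("messageIds", "BPMFFit", function(x) x@messageIds)

#' @rdname predictRating
#' @export
setMethod("predictRating", "BPMFFit", function(model, user, message) {
  n <- max(length(user), length(message))
  user <- rep_len(as.character(user), n)
  message <- rep_len(as.character(message), n)
  uidx <- match(user, model@userIds)
  midx <- match(message, model@messageIds)
  if (anyNA(uidx)) stop("unknown user id(s): ",
                        paste(unique(user[is.na(uidx)]), collapse = ", "),
                        call. = FALSE)
  if (anyNA(midx)) stop("unknown message id(s): ",
                        paste(unique(message[is.na(midx)]), collapse = ", "),
                        call. = FALSE)
  S <- dim(model@userFactors)[1]; D <- dim(model@userFactors)[3]
  acc <- numeric(n)
  for (s in seq_len(S)) {
    Us <- matrix(model@userFactors[s, uidx, ], n, D)
    Vs <- matrix(model@itemFactors[s, midx, ], n, D)
    acc <- acc + rowSums(Us * Vs)
  }
  clipRating(acc / S + model@offset)
})

#' @rdname inferNewUser
#' @export
setMethod("inferNewUser", "BPMFFit", function(model, messages, ratings) {
  S <- dim(model@userFactors)[1]; D <- dim(model@userFactors)[3]
  if (length(messages) == 0L) return(matrix(0, S, D))
  if (length(messages) != length(ratings))
    stop("messages and ratings must have equal length", call. = FALSE)
  midx <- match(as.character(messages), model@messageIds)
  if (anyNA(midx))
    stop("observed message(s) unknown to the model: ",
         paste(unique(messages[is.na(midx)]), collapse = ", "), call. = FALSE)
  y <- as.numeric(ratings) - model@offset
  k <- length(midx)
  A <- model@itemFactors[, midx, , drop = FALSE]       # S x k x D
  ## per-sample Gram matrices and right-hand sides, batched over samples
  Xp <- array(0, c(S, D, D))
  rhs <- matrix(0, S, D)
  for (d1 in seq_len(D)) {
    rhs[, d1] <- matrix(A[, , d1], S, k) %*% y
    for (d2 in d1:D) {
      v <- rowSums(matrix(A[, , d1] * A[, , d2], S, k))
      Xp[, d1, d2] <- v; Xp[, d2, d1] <- v
    }
  }
  rhs <- model@alpha * rhs
  for (d1 in seq_len(D)) for (d2 in seq_len(D))
    rhs[, d1] <- rhs[, d1] + model@userLambda[d1, d2, ] * model@userMu[, d2]
  prec <- model@alpha * Xp
  for (d1 in seq_len(D)) for (d2 in seq_len(D))
    prec[, d1, d2] <- prec[, d1, d2] + model@userLambda[d1, d2, ]
  if (D == 1L) return(matrix(rhs[, 1] / prec[, 1, 1], S, 1))
  if (D == 2L) {
    det <- prec[, 1, 1] * prec[, 2, 2] - prec[, 1, 2]^2
    return(cbind((prec[, 2, 2] * rhs[, 1] - prec[, 1, 2] * rhs[, 2]) / det,
                 (prec[, 1, 1] * rhs[, 2] - prec[, 1, 2] * rhs[, 1]) / det))
  }
  out <- matrix(0, S, D)
  for (s in seq_len(S))
    out[s, ] <- solve(matrix(prec[s, , ], D, D), rhs[s, ])
  out
})

#' @rdname predictNewUser
#' @export
setMethod("predictNewUser", "BPMFFit", function(model, userFactors, message) {
  S <- dim(model@userFactors)[1]; D <- dim(model@userFactors)[3]
  stopifnot(is.matrix(userFactors), nrow(userFactors) == S, ncol(userFactors) == D)
  midx <- match(as.character(message), model@messageIds)
  if (anyNA(midx))
    stop("unknown message id(s): ",
         paste(unique(message[is.na(midx)]), collapse = ", "), call. = FALSE)
  n <- length(midx)
  ## mean over samples of u_s . v_s as one inner product on the stacked layout
  B <- aperm(model@itemFactors[, midx, , drop = FALSE], c(1, 3, 2))
  dim(B) <- c(S * D, n)
  clipRating(drop(crossprod(as.vector(userFactors), B)) / S + model@offset)
})

#' Save or load a fitted BPMF model as a structured text archive
#'
#' The archive is a single JSON document holding the configuration, index
#' vectors, offset and flattened factor/hyperparameter arrays.
#'
#' @param model A [BPMFFit-class].
#' @param path File path (".json").
#' @return `saveBPMF` returns `path` invisibly; `readBPMF` a [BPMFFit-class].
#' @export
saveBPMF <- function(model, path) {
  stopifnot(is(model, "BPMFFit"))
  obj <- list(config = model@config, offset = model@offset, alpha = model@alpha,
              userIds = model@userIds, messageIds = model@messageIds,
              dims = list(user = dim(model@userFactors),
                          item = dim(model@itemFactors)),
              userFactors = as.vector(model@userFactors),
              itemFactors = as.vector(model@itemFactors),
              userMu = as.vector(model@userMu), itemMu = as.vector(model@itemMu),
              userLambda = as.vector(model@userLambda),
              itemLambda = as.vector(model@itemLambda))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveBPMF
#' @export
readBPMF <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  du <- as.integer(obj$dims$user); di <- as.integer(obj$dims$item)
  D <- du[3]; S <- du[1]
  new("BPMFFit",
      userFactors = array(obj$userFactors, du),
      itemFactors = array(obj$itemFactors, di),
      userMu = matrix(obj$userMu, S, D), itemMu = matrix(obj$itemMu, S, D),
      userLambda = array(obj$userLambda, c(D, D, S)),
      itemLambda = array(obj$itemLambda, c(D, D, S)),
      offset = obj$offset, alpha = obj$alpha,
      userIds = obj$userIds, messageIds = obj$messageIds,
      config = obj$config)
}
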