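## Rating-prediction and ranking metrics: RMSE, Kendall tau-b with tie
## correction, and normalized discounted cumulative gain with pessimistic tie
## handling.

#' Root mean squared error
#'
#' @param predicted,actual Equal-length nonempty numeric vectors.
#' @return \code{sqrt(mean((predicted - actual)^2))}.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length", call. = FALSE)
  if (length(predicted) == 0L) stop("rmse of empty vectors is undefined", call. = FALSE)
  sqrt(mean((predicted - actual)^2))
}

#' Kendall rank correlation tau-b
#'
#' Tie-corrected rank correlation
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' where C and D count concordant and discordant pairs, \eqn{n_0 = n(n-1)/2},
#' and \eqn{n_1}, \eqn{n_2} count tied pairs within x and within y. When
#' either vector is entirely tied the coefficient is undefined and
#' \code{NA} is returned with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return A value in [-1, 1], or \code{NA}.
#' @examples
#' kendallTauB(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 4/6
#' @export
kendallTauB <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("kendallTauB needs at least two observations", call. = FALSE)
  pairs <- utils::combn(n, 2)
  dx <- sign(x[pairs[1, ]] - x[pairs[2, ]])
  dy <- sign(y[pairs[1, ]] - y[pairs[2, ]])
  C <- sum(dx * dy > 0)
  D <- sum(dx * dy < 0)
  n0 <- n * (n - 1) / 2
  tieCount <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tieCount(x); n2 <- tieCount(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    warning("tau-b undefined: a vector is entirely tied")
    return(NA_real_)
  }
  (C - D) / denom
}

#' Normalized discounted cumulative gain
#'
#' Ranks items by predicted score and accumulates exponential gains
#' \eqn{(2^{rel} - 1)/\log_2(rank + 1)} to the given depth, normalized by the
#' DCG of the ideal (relevance-sorted) ordering. Ties in the predicted scores
#' are broken pessimistically (worst-case true relevance first), so reported
#' NDCG never benefits from ties. All-zero relevance is undefined and yields
#' \code{NA} with a warning.
#'
#' @param predicted Numeric scores used to rank the items.
#' @param relevance Nonnegative true relevances (here: the true ratings).
#' @param depth Ranking depth (default: all items).
#' @return A value in (0, 1], or \code{NA}.
#' @examples
#' ndcg(c(3, 2, 1), c(3, 2, 1))  # ideal order: 1
#' @export
ndcg <- function(predicted, relevance, depth = length(relevance)) {
  if (length(predicted) != length(relevance))
    stop("predicted and relevance must have equal length", call. = FALSE)
  if (any(relevance < 0)) stop("relevances must be nonnegative", call. = FALSE)
  if (all(relevance == 0)) {
    warning("ndcg undefined: all relevances are zero")
    return(NA_real_)
  }
  depth <- min(depth, length(relevance))
  dcgAt <- function(rel) sum((2^rel[seq_len(depth)] - 1) /
                               log2(seq_len(depth) + 1))
  sys <- order(-predicted, relevance)           # pessimistic tie-break
  ideal <- order(-relevance)
  dcgAt(relevance[sys]) / dcgAt(relevance[ideal])
}
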