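## Small fixtures built in code.

## A three-message library with one message per distinct shape of coding.
tinyLib <- function() {
  MessageLibrary(
    id = c("m1", "m2", "m3"),
    text = c("Quitting gets easier every day",
             "Ask your doctor about the patch",
             "Write down your reasons to quit"),
    source = c("PEER", "EXPERT", "EXPERT"),
    stages = list("THINKING", c("SET_QUIT_DATE", "QUIT_TODAY"),
                  readinessStages()),
    tags = list("MOTIVATIONAL_CONTENT", "BEHAVIORAL_TREATMENT",
                c("MOTIVATIONAL_CONTENT", "GOAL_SETTING")))
}

## A dense five-user toy rating matrix (0 = unrated).
toyMatrix <- function() {
  m <- rbind(c(5, 4, 0, 2, 1, 3),
             c(5, 4, 4, 2, 1, 0),
             c(1, 2, 3, 4, 5, 4),
             c(3, 3, 3, 3, 0, 3),
             c(4, 0, 4, 3, 2, 2))
  dimnames(m) <- list(paste0("u", 1:5), paste0("m", 1:6))
  m
}

toyDataset <- function(m = toyMatrix()) {
  idx <- which(m != 0, arr.ind = TRUE)
  RatingDataset(data.frame(user = rownames(m)[idx[, 1]],
                           message = colnames(m)[idx[, 2]],
                           rating = m[idx]),
                userIds = rownames(m), messageIds = colnames(m))
}

## Hand-assembled single-sample posterior for exact prediction arithmetic.
manualBPMF <- function(itemFactors, userLambda = diag(ncol(itemFactors)),
                       userMu = rep(0, ncol(itemFactors)), offset = 3,
                       alpha = 2, nSamples = 1) {
  D <- ncol(itemFactors); M <- nrow(itemFactors); S <- nSamples
  iF <- array(0, c(S, M, D))
  for (s in seq_len(S)) iF[s, , ] <- itemFactors
  uL <- array(0, c(D, D, S)); for (s in seq_len(S)) uL[, , s] <- userLambda
  new("BPMFFit",
      userFactors = array(0, c(S, 1, D)), itemFactors = iF,
      userMu = matrix(rep(userMu, each = S), S, D),
      itemMu = matrix(0, S, D),
      userLambda = uL, itemLambda = uL,
      offset = offset, alpha = alpha,
      userIds = "u-train", messageIds = rownames(itemFactors),
      config = list(latentDim = D, nSamples = S))
}

## Independent pair-enumeration oracle for Kendall tau-b.
tauOracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- x[i] - x[j]; b <- y[i] - y[j]
    if (a == 0) tx <- tx + 1
    if (b == 0) ty <- ty + 1
    if (a * b > 0) C <- C + 1
    if (a * b < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) NA_real_ else (C - D) / den
}

## Enumeration oracle for NDCG: worst-case DCG over orderings consistent with
## the predicted scores, over the best achievable DCG of any ordering.
ndcgOracle <- function(predicted, relevance, depth = length(relevance)) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  dcg <- function(ord) {
    r <- relevance[ord][seq_len(depth)]
    sum((2^r - 1) / log2(seq_len(depth) + 1))
  }
  all <- perms(seq_along(relevance))
  ideal <- max(vapply(all, dcg, numeric(1)))
  consistent <- Filter(function(ord) !is.unsorted(rev(predicted[ord])), all)
  sys <- min(vapply(consistent, dcg, numeric(1)))
  sys / ideal
}
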