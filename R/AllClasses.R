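#' @import methods
#' @importFrom stats rWishart rnorm runif rbinom sd var cor t.test chisq.test
#'   binom.test pnorm plogis qlogis setNames complete.cases
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' The five-level readiness-to-quit ladder
#'
#' Ordered levels of the self-assessed readiness-to-quit ladder used both to
#' code messages and to record participant stage: not thinking of quitting,
#' thinking of quitting, set a quit date, quit today, already quit. "Moving
#' up" the ladder means a strictly higher level.
#'
#' @return Character vector of the five stage codes, in ladder order.
#' @examples
#' readinessStages()
#' @export
readinessStages <- function() {
  c("NOT_THINKING", "THINKING", "SET_QUIT_DATE", "QUIT_TODAY", "ALREADY_QUIT")
}

#' Position of a stage on the readiness ladder
#'
#' @param stage Character vector of stage codes.
#' @return Integer vector of ladder positions (1 = lowest).
#' @examples
#' stageIndex("THINKING")
#' @export
stageIndex <- function(stage) {
  idx <- match(toupper(as.character(stage)), readinessStages())
  if (anyNA(idx))
    stop("unknown readiness stage: ",
         paste(unique(stage[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

## ---------------------------------------------------------------------------
## MessageLibrary

#' MessageLibrary: a library of coded motivational messages
#'
#' Container for a motivational message library. Each message carries a unique
#' id, its text, a source (expert- or peer-written), the set of
#' readiness-to-quit stages it is coded for, and an open vocabulary of content
#' tags (e.g. \code{MOTIVATIONAL_CONTENT}, \code{BEHAVIORAL_TREATMENT}, or
#' behaviour-theory construct labels).
#'
#' @slot table A \code{data.frame} with columns \code{id}, \code{text},
#'   \code{source} and list columns \code{stages}, \code{tags}.
#' @seealso [MessageLibrary()], [readMessageLibrary()], [filterByStage()],
#'   [tagProportions()]
#' @slot stageMask Logical matrix (5 x nMessages) caching stage membership,
#'   rows in [readinessStages()] order; maintained by the constructor.
#' @name MessageLibrary-class
#' @rdname MessageLibrary-class
#' @exportClass MessageLibrary
setClass("MessageLibrary", slots = c(table = "data.frame", stageMask = "matrix"))

setValidity("MessageLibrary", function(object) {
  tab <- object@table
  need <- c("id", "text", "source", "stages", "tags")
  if (!all(need %in% names(tab)))
    return(paste("missing columns:", paste(setdiff(need, names(tab)), collapse = ", ")))
  if (anyDuplicated(tab$id))
    return(paste("duplicate message id(s):",
                 paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
  if (any(!nzchar(tab$text)))
    return("every message must have nonempty text")
  if (!all(tab$source %in% c("EXPERT", "PEER")))
    return("source must be EXPERT or PEER")
  if (!is.list(tab$stages) || !is.list(tab$tags))
    return("stages and tags must be list columns")
  if (any(lengths(tab$stages) == 0L))
    return("every message must be coded for at least one readiness stage")
  bad <- !vapply(tab$stages, function(s) all(s %in% readinessStages()), logical(1))
  if (any(bad))
    return("stages contain codes outside the five-level ladder")
  if (!identical(dim(object@stageMask), c(5L, nrow(tab))))
    return("stage mask out of step with the message table")
  TRUE
})

## ---------------------------------------------------------------------------
## RatingDataset

#' RatingDataset: sparse explicit message ratings
#'
#' Sparse collection of (user, message, rating) triplets on the five-point
#' Likert scale, with dense user and message indices. Ratings are integers in
#' 1..5 by default; continuous values in [1, 5] are accepted so that noise-free
#' generator output can be used in factor-recovery checks.
#'
#' @slot ratings A \code{data.frame} with columns \code{user}, \code{message},
#'   \code{rating} and optionally \code{day}.
#' @slot userIds Character vector: the user index (row order).
#' @slot messageIds Character vector: the message index (column order).
#' @seealso [RatingDataset()], [ratingMatrix()], [readRatings()]
#' @name RatingDataset-class
#' @rdname RatingDataset-class
#' @exportClass RatingDataset
setClass("RatingDataset",
         slots = c(ratings = "data.frame", userIds = "character",
                   messageIds = "character"))

setValidity("RatingDataset", function(object) {
  r <- object@ratings
  if (!all(c("user", "message", "rating") %in% names(r)))
    return("ratings needs columns user, message, rating")
  if (nrow(r) == 0L) return("dataset must contain at least one rating")
  if (any(!is.finite(r$rating)) || any(r$rating < 1 - 1e-9) || any(r$rating > 5 + 1e-9))
    return("ratings must lie in [1, 5]")
  if (anyDuplicated(paste(r$user, r$message, sep = "\r")))
    return("duplicate (user, message) pair")
  if (anyDuplicated(object@userIds) || anyDuplicated(object@messageIds))
    return("user/message indices must be duplicate free")
  if (!all(r$user %in% object@userIds))
    return("ratings reference users absent from the user index")
  if (!all(r$message %in% object@messageIds))
    return("ratings reference messages absent from the message index")
  if ("day" %in% names(r) && any(!is.na(r$day) & r$day < 0))
    return("day indices must be nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Factor models

#' BPMFFit: posterior samples of a Bayesian matrix-factorization model
#'
#' Result of [fitBPMF()]: retained Gibbs samples of the latent user and item
#' factor matrices together with the per-sample Normal-Wishart hyperparameter
#' draws needed for cold-start inference of a new user's factor, the global
#' rating offset (training mean), and the observation precision.
#'
#' @slot userFactors Array \code{nSamples x nUsers x D}.
#' @slot itemFactors Array \code{nSamples x nMessages x D}.
#' @slot userMu,itemMu Matrices \code{nSamples x D}: per-sample population means.
#' @slot userLambda,itemLambda Arrays \code{D x D x nSamples}: per-sample
#'   population precision matrices.
#' @slot offset Numeric: global rating offset (training mean).
#' @slot alpha Numeric: observation noise precision.
#' @slot userIds,messageIds Character: index order of factors.
#' @slot config List of fitting settings (latentDim, nSamples, burnIn, prior, seed).
#' @name BPMFFit-class
#' @rdname BPMFFit-class
#' @exportClass BPMFFit
setClass("BPMFFit",
         slots = c(userFactors = "array", itemFactors = "array",
                   userMu = "matrix", itemMu = "matrix",
                   userLambda = "array", itemLambda = "array",
                   offset = "numeric", alpha = "numeric",
                   userIds = "character", messageIds = "character",
                   config = "list"))

setValidity("BPMFFit", function(object) {
  du <- dim(object@userFactors); di <- dim(object@itemFactors)
  if (length(du) != 3L || length(di) != 3L)
    return("factor slots must be 3-d arrays (sample x entity x dimension)")
  if (du[1] != di[1]) return("user and item sample counts differ")
  if (du[1] < 1L) return("at least one posterior sample is required")
  if (du[2] != length(object@userIds) || di[2] != length(object@messageIds))
    return("factor array extents do not match the id vectors")
  if (du[3] != di[3]) return("user and item latent dimensions differ")
  if (!all(is.finite(object@userFactors)) || !all(is.finite(object@itemFactors)))
    return("factor samples must be finite")
  TRUE
})

#' PMFFit: MAP probabilistic matrix factorization point estimate
#'
#' Result of [fitPMF()]: point estimates of user and item factors obtained by
#' alternating ridge least squares, with the global offset, the regularization
#' weight, and the trace of the (monotone non-increasing) penalized objective.
#'
#' @slot userFactors Matrix \code{nUsers x D}.
#' @slot itemFactors Matrix \code{nMessages x D}.
#' @slot offset,lambda Numeric scalars.
#' @slot objective Numeric vector: objective value after each alternation.
#' @slot userIds,messageIds Character index vectors.
#' @slot config List of fitting settings.
#' @name PMFFit-class
#' @rdname PMFFit-class
#' @exportClass PMFFit
setClass("PMFFit",
         slots = c(userFactors = "matrix", itemFactors = "matrix",
                   offset = "numeric", lambda = "numeric",
                   objective = "numeric",
                   userIds = "character", messageIds = "character",
                   config = "list"))

## ---------------------------------------------------------------------------
## Scheduler

#' Policy: a daily message-selection policy
#'
#' Either the recommender policy (\code{PERSPECT}), which ranks stage-matched
#' unsent messages by predicted rating under a fitted [BPMFFit-class] model, or
#' the rule-based standard comparator (\code{RULE_BASED}), which draws a
#' stage-matched unsent message uniformly at random from a reproducible seeded
#' stream and ignores ratings.
#'
#' @slot kind \code{"PERSPECT"} or \code{"RULE_BASED"}.
#' @slot model A [BPMFFit-class] for \code{PERSPECT}; \code{NULL} otherwise.
#' @slot seed Integer seed for the comparator's selection stream.
#' @seealso [perspectPolicy()], [ruleBasedPolicy()], [selectNext()]
#' @name Policy-class
#' @rdname Policy-class
#' @exportClass Policy
setClass("Policy", slots = c(kind = "character", model = "ANY", seed = "integer"))

setValidity("Policy", function(object) {
  if (!object@kind %in% c("PERSPECT", "RULE_BASED"))
    return("kind must be PERSPECT or RULE_BASED")
  if (object@kind == "PERSPECT" && !is(object@model, "BPMFFit"))
    return("the PERSPECT policy requires a fitted BPMF model")
  TRUE
})

#' SessionState: one user's message-delivery history
#'
#' Mutable-by-copy record of a messaging session: the ordered list of sent
#' message ids, the (message, rating, day) log, the day counter (equal to the
#' number of messages sent), and, for the recommender policy, the current
#' per-posterior-sample user factor.
#'
#' @slot user Character user id.
#' @slot stage Character readiness stage.
#' @slot sent Character vector of sent message ids (no duplicates).
#' @slot log \code{data.frame} with columns day, message, predicted, rating.
#' @slot day Integer day counter.
#' @slot userFactors \code{nSamples x D} matrix or \code{NULL}.
#' @seealso [newSession()], [runSession()]
#' @name SessionState-class
#' @rdname SessionState-class
#' @exportClass SessionState
setClass("SessionState",
         slots = c(user = "character", stage = "character", sent = "character",
                   log = "data.frame", day = "integer", userFactors = "ANY"))

setValidity("SessionState", function(object) {
  if (anyDuplicated(object@sent)) return("a message was sent twice")
  if (object@day != length(object@sent)) return("day counter must equal number sent")
  if (!all(object@log$message %in% object@sent))
    return("rated messages must have been sent")
  if (!object@stage %in% readinessStages()) return("unknown readiness stage")
  TRUE
})
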