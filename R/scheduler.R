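## Daily message selection for both trial arms. The recommender policy
## stage-filters the unsent messages, ranks candidates by predicted rating,
## sends the best, and re-infers the user's factor after each rating. The
## rule-based standard comparator draws a stage-matched unsent message from a
## reproducible seeded stream and never reacts to ratings.

#' Recommender (PERSPeCT) delivery policy
#'
#' @param model A fitted [BPMFFit-class].
#' @param seed Integer seed (kept for interface symmetry; selection itself is
#'   deterministic given the model and history).
#' @return A [Policy-class].
#' @export
perspectPolicy <- function(model, seed = 1) {
  new("Policy", kind = "PERSPECT", model = model, seed = as.integer(seed))
}

#' Rule-based standard-CTHC delivery policy
#'
#' Stage-matched selection with a seeded uniform draw (without replacement)
#' among candidates; ratings are recorded for analysis only and never change
#' the selection stream.
#'
#' @param seed Integer seed of the selection stream.
#' @return A [Policy-class].
#' @export
ruleBasedPolicy <- function(seed = 1) {
  new("Policy", kind = "RULE_BASED", model = NULL, seed = as.integer(seed))
}

#' Start a messaging session
#'
#' @param user User id.
#' @param stage The user's readiness stage (see [readinessStages()]).
#' @return A fresh [SessionState-class].
#' @export
newSession <- function(user, stage) {
  new("SessionState", user = as.character(user),
      stage = readinessStages()[stageIndex(stage)], sent = character(0),
      log = data.frame(day = integer(0), message = character(0),
                       predicted = numeric(0), rating = numeric(0),
                       stringsAsFactors = FALSE),
      day = 0L, userFactors = NULL)
}

setMethod("show", "SessionState", function(object) {
  cat(sprintf("SessionState for %s (stage %s): day %d, %d sent, %d rated\n",
              object@user, object@stage, object@day, length(object@sent),
              nrow(object@log)))
})

#' Session log accessor
#'
#' @param state A [SessionState-class].
#' @return \code{data.frame} with one row per rated message: day, message,
#'   predicted (NA under the rule-based policy), rating.
#' @export
sessionLog <- function(state) {
  stopifnot(is(state, "SessionState"))
  state@log
}

## Stage-matched unsent candidates, relaxed outward over adjacent ladder
## levels and finally to all unsent messages.
candidateMessages <- function(state, lib) {
  ids <- messageIds(lib)
  unsent <- !(ids %in% state@sent)
  if (!any(unsent)) return(character(0))
  pos <- match(state@stage, readinessStages())
  for (d in 0:4) {
    lvl <- which(abs(seq_len(5) - pos) <= d)
    hit <- unsent & (colSums(lib@stageMask[lvl, , drop = FALSE]) > 0L)
    if (any(hit)) return(ids[hit])
  }
  ids[unsent]
}

#' Select the next message to send
#'
#' Candidates are the stage-matched unsent messages (relaxed to adjacent
#' ladder levels outward, then to all unsent, if empty). The recommender
#' policy returns the candidate with the highest predicted rating (ties
#' broken by lowest message id); the rule-based policy draws uniformly from
#' the candidates using a seed derived from its stream seed and the day, so
#' its sequence is reproducible and independent of ratings.
#'
#' @param state A [SessionState-class].
#' @param policy A [Policy-class].
#' @param lib A [MessageLibrary-class].
#' @return A list with \code{message} (the selected id) and \code{predicted}
#'   (the predicted rating; NA under the rule-based policy).
#' @export
selectNext <- function(state, policy, lib) {
  stopifnot(is(state, "SessionState"), is(policy, "Policy"))
  cand <- candidateMessages(state, lib)
  if (!length(cand))
    stop(structure(class = c("sessionComplete", "error", "condition"),
                   list(message = "message library exhausted", call = NULL)))
  if (policy@kind == "PERSPECT") {
    model <- policy@model
    pred <- if (is.null(state@userFactors))
      rep(clipRating(model@offset), length(cand))
    else predictNewUser(model, state@userFactors, cand)
    pick <- order(-pred, cand)[1L]
    list(message = cand[pick], predicted = pred[pick])
  } else {
    pick <- withSeed(policy@seed + 131L * (state@day + 1L),
                     sample(length(cand), 1L))
    list(message = cand[pick], predicted = NA_real_)
  }
}

#' Mark a message as sent
#'
#' @param state A [SessionState-class].
#' @param message The message id just sent.
#' @param predicted Its predicted rating at selection time (optional).
#' @return The updated [SessionState-class] (day advanced by one).
#' @export
sendMessage <- function(state, message, predicted = NA_real_) {
  if (message %in% state@sent)
    stop("message ", message, " was already sent", call. = FALSE)
  state@sent <- c(state@sent, message)
  state@day <- state@day + 1L
  attr(state@log, "pendingPredicted")[message] <- predicted
  state
}

#' Record a user's rating of a sent message
#'
#' Appends the rating to the session log. Under the recommender policy the
#' user's factor is re-inferred from all of this user's ratings so far (full
#' cold-start re-inference after every rating); under the rule-based policy
#' ratings are recorded for analysis only.
#'
#' @param state A [SessionState-class].
#' @param message A sent, not-yet-rated message id.
#' @param rating Integer rating in 1..5.
#' @param policy The active [Policy-class].
#' @return The updated [SessionState-class].
#' @export
recordRating <- function(state, message, rating, policy) {
  stopifnot(is(state, "SessionState"), is(policy, "Policy"))
  if (!message %in% state@sent)
    stop("cannot rate unsent message ", message, call. = FALSE)
  if (message %in% state@log$message)
    stop("message ", message, " was already rated", call. = FALSE)
  if (!is.numeric(rating) || rating < 1 || rating > 5)
    stop("rating must lie in 1..5", call. = FALSE)
  pending <- attr(state@log, "pendingPredicted")
  predicted <- if (!is.null(pending) && message %in% names(pending))
    unname(pending[message]) else NA_real_
  state@log <- rbind(state@log,
                     data.frame(day = match(message, state@sent),
                                message = message, predicted = predicted,
                                rating = as.numeric(rating),
                                stringsAsFactors = FALSE))
  attr(state@log, "pendingPredicted") <- pending
  if (policy@kind == "PERSPECT")
    state@userFactors <- inferNewUser(policy@model, state@log$message,
                                      state@log$rating)
  state
}

#' Run a full messaging session
#'
#' Alternates [selectNext()], the rating oracle, and [recordRating()] until
#' \code{n} messages have been rated. Deterministic for fixed policy and
#' oracle seeds.
#'
#' @param user,stage The participant's id and readiness stage.
#' @param policy A [Policy-class].
#' @param lib A [MessageLibrary-class] with at least \code{n} messages.
#' @param ratingOracle Function \code{(message, day) -> rating in 1..5}
#'   standing in for the participant (see [latentRatingOracle()]).
#' @param n Number of messages to deliver and rate (default 30).
#' @return The final [SessionState-class].
#' @export
runSession <- function(user, stage, policy, lib, ratingOracle, n = 30) {
  if (nMessages(lib) < n)
    stop(sprintf("library has %d messages; session needs %d", nMessages(lib), n),
         call. = FALSE)
  state <- newSession(user, stage)
  for (i in seq_len(n)) {
    sel <- selectNext(state, policy, lib)
    state <- sendMessage(state, sel$message, sel$predicted)
    r <- ratingOracle(sel$message, state@day)
    state <- recordRating(state, sel$message, r, policy)
  }
  state
}

#' Simulated participant rating oracle with known latent preferences
#'
#' Rates message \code{m} as \code{round(u . v_m + offset + noise)} clipped to
#' 1..5, where \code{u} is the participant's true preference vector and
#' \code{v_m} the true item factor — the same ordinal model the rating
#' generator uses. Deterministic per (seed, day).
#'
#' @param userFactor Numeric preference vector.
#' @param itemFactors True item factor matrix with rownames = message ids.
#' @param offset Global offset of the continuous score.
#' @param noiseSd Rating noise SD.
#' @param seed Integer seed.
#' @return A function \code{(message, day) -> rating}.
#' @export
latentRatingOracle <- function(userFactor, itemFactors, offset = 3,
                               noiseSd = 0.5, seed = 1) {
  force(userFactor); force(itemFactors)
  function(message, day) {
    v <- itemFactors[message, ]
    withSeed(seed + 613L * day,
             clipRating(round(sum(userFactor * v) + offset + rnorm(1, 0, noiseSd))))
  }
}

#' True mean latent score of the messages sent in a session
#'
#' Policy-value summary: the mean of \code{u . v_m + offset} over the sent
#' messages, under the participant's true preferences.
#'
#' @param state A [SessionState-class].
#' @param userFactor,itemFactors,offset The true latent world.
#' @return A single number.
#' @export
sentMeanTrueScore <- function(state, userFactor, itemFactors, offset = 3) {
  mean(itemFactors[state@sent, , drop = FALSE] %*% userFactor + offset)
}
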