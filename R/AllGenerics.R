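#' Number of users indexed by an object
#' @param x A [RatingDataset-class] or model object.
#' @return Integer count.
#' @export
setGeneric("nUsers", function(x) standardGeneric("nUsers"))

#' Number of messages indexed by an object
#' @param x A [MessageLibrary-class], [RatingDataset-class] or model object.
#' @return Integer count.
#' @export
setGeneric("nMessages", function(x) standardGeneric("nMessages"))

#' Number of ratings in a dataset
#' @param x A [RatingDataset-class].
#' @return Integer count.
#' @export
setGeneric("nRatings", function(x) standardGeneric("nRatings"))

#' User ids of an object
#' @param x A [RatingDataset-class] or model object.
#' @return Character vector.
#' @export
setGeneric("userIds", function(x) standardGeneric("userIds"))

#' Message ids of an object
#' @param x A [MessageLibrary-class], [RatingDataset-class] or model object.
#' @return Character vector.
#' @export
setGeneric("messageIds", function(x) standardGeneric("messageIds"))

#' Predict the rating a known user would give a known message
#'
#' For a [BPMFFit-class], the prediction is the mean over posterior samples of
#' the user-item factor inner product plus the global offset; for a
#' [PMFFit-class], the point-estimate inner product plus offset. Predictions
#' are clipped to the rating scale [1, 5].
#'
#' @param model A fitted factor model.
#' @param user,message Character vectors of equal length (or length 1,
#'   recycled) naming users/messages known to the model.
#' @return Numeric vector of predicted ratings in [1, 5].
#' @export
setGeneric("predictRating", function(model, user, message)
  standardGeneric("predictRating"))

#' Infer a new user's latent factor with item parameters frozen
#'
#' Cold-start inference: given a fitted model and the observed ratings of a
#' user that was not in training, compute the user-specific factor while all
#' non-user-specific parameters stay frozen. For [BPMFFit-class], each
#' posterior sample yields the conditional Gaussian posterior mean of the new
#' user's factor given that sample's item factors and hyperparameters (a ridge
#' regression with prior precision from the sampled population precision); for
#' [PMFFit-class], a single ridge solve against the point-estimate item
#' factors.
#'
#' With zero observed ratings the factor falls back to zero, so every
#' prediction equals the global offset.
#'
#' @param model A fitted factor model.
#' @param messages Character vector of rated message ids (all known to the model).
#' @param ratings Numeric vector of the same length, ratings in [1, 5].
#' @return For BPMF, an \code{nSamples x D} matrix; for PMF, a length-D vector.
#' @seealso [predictNewUser()]
#' @export
setGeneric("inferNewUser", function(model, messages, ratings)
  standardGeneric("inferNewUser"))

#' Predict ratings for a new user from inferred factors
#'
#' @param model A fitted factor model.
#' @param userFactors The result of [inferNewUser()] for that model.
#' @param message Character vector of target message ids.
#' @return Numeric vector of predicted ratings in [1, 5].
#' @export
setGeneric("predictNewUser", function(model, userFactors, message)
  standardGeneric("predictNewUser"))

#' Filter a message library by readiness stage
#'
#' Returns exactly the messages coded for the queried readiness stage,
#' preserving order. This is the stage-matching constraint both delivery
#' policies obey: messages are chosen only from among those matching the
#' participant's readiness to quit.
#'
#' @param lib A [MessageLibrary-class].
#' @param stage A single readiness stage code (see [readinessStages()]).
#' @return A [MessageLibrary-class] (possibly empty).
#' @export
setGeneric("filterByStage", function(lib, stage) standardGeneric("filterByStage"))
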