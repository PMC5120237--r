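## Sparse explicit-rating dataset: construction, accessors, file round-trip.

#' Construct a rating dataset
#'
#' @param ratings A \code{data.frame} with columns \code{user},
#'   \code{message}, \code{rating} (in [1, 5]) and optionally \code{day}.
#' @param userIds,messageIds Optional index vectors; default to the users and
#'   messages observed in \code{ratings}, in order of first appearance. A
#'   superset may be supplied (e.g. the full message library) but every index
#'   entry must be unique.
#' @return A [RatingDataset-class].
#' @examples
#' rd <- RatingDataset(data.frame(user = c("u1", "u1", "u2"),
#'                                message = c("m1", "m2", "m1"),
#'                                rating = c(4, 5, 3)))
#' nRatings(rd)
#' @export
RatingDataset <- function(ratings, userIds = NULL, messageIds = NULL) {
  ratings$user <- as.character(ratings$user)
  ratings$message <- as.character(ratings$message)
  ratings$rating <- as.numeric(ratings$rating)
  new("RatingDataset", ratings = ratings,
      userIds = as.character(userIds %||% unique(ratings$user)),
      messageIds = as.character(messageIds %||% unique(ratings$message)))
}

#' @describeIn RatingDataset-class number of indexed users
#' @param x A RatingDataset.
#' @export
setMethod("nUsers", "RatingDataset", function(x) length(x@userIds))

#' @describeIn RatingDataset-class number of indexed messages
#' @export
setMethod("nMessages", "RatingDataset", function(x) length(x@messageIds))

#' @describeIn RatingDataset-class number of rating triplets
#' @export
setMethod("nRatings", "RatingDataset", function(x) nrow(x@ratings))

#' @describeIn RatingDataset-class user index
#' @export
setMethod("userIds", "RatingDataset", function(x) x@userIds)

#' @describeIn RatingDataset-class message index
#' @export
setMethod("messageIds", "RatingDataset", function(x) x@messageIds)

setMethod("show", "RatingDataset", function(object) {
  cat(sprintf("RatingDataset: %d ratings, %d users x %d messages (density %.1f%%)\n",
              nRatings(object), nUsers(object), nMessages(object),
              100 * nRatings(object) / (nUsers(object) * nMessages(object))))
  cat("  mean rating:", round(mean(object@ratings$rating), 3), "\n")
})

#' Rating triplets accessor
#'
#' @param data A [RatingDataset-class].
#' @return The triplet \code{data.frame}.
#' @export
ratingTriplets <- function(data) {
  stopifnot(is(data, "RatingDataset"))
  data@ratings
}

#' Sparse user-by-message rating matrix
#'
#' @param data A [RatingDataset-class].
#' @return A \code{\link[Matrix]{sparseMatrix}} (users x messages) whose
#'   stored entries are the ratings; structural zeros mean "not rated"
#'   (a valid rating is never 0).
#' @export
ratingMatrix <- function(data) {
  stopifnot(is(data, "RatingDataset"))
  r <- data@ratings
  Matrix::sparseMatrix(i = match(r$user, data@userIds),
                       j = match(r$message, data@messageIds),
                       x = r$rating,
                       dims = c(nUsers(data), nMessages(data)),
                       dimnames = list(data@userIds, data@messageIds))
}

#' Restrict a rating dataset to a subset of users
#'
#' Used by the strong-generalization protocol to carve train/test user folds.
#'
#' @param data A [RatingDataset-class].
#' @param users Character vector of user ids to keep.
#' @param messageIds Optional message index for the result (defaults to the
#'   parent's full message index, so item columns stay aligned).
#' @return A [RatingDataset-class].
#' @export
subsetUsers <- function(data, users, messageIds = NULL) {
  stopifnot(is(data, "RatingDataset"))
  keep <- data@ratings$user %in% users
  RatingDataset(data@ratings[keep, , drop = FALSE],
                userIds = intersect(data@userIds, users),
                messageIds = messageIds %||% data@messageIds)
}

#' Read ratings from a delimited text file
#'
#' Expects a header \code{user,message,rating} with an optional \code{day}
#' column.
#'
#' @param path CSV path.
#' @param messageIds Optional message index (e.g. from the library).
#' @return A [RatingDataset-class].
#' @export
readRatings <- function(path, messageIds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("user", "message", "rating") %in% names(tab)))
    stop("ratings file needs columns user, message, rating", call. = FALSE)
  RatingDataset(tab, messageIds = messageIds)
}

#' Write ratings to a delimited text file
#'
#' @param data A [RatingDataset-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeRatings <- function(data, path) {
  stopifnot(is(data, "RatingDataset"))
  write.csv(data@ratings, path, row.names = FALSE)
  invisible(path)
}
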