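## Message library: construction, file round-trip, stage filtering, tag audits.

#' Construct a message library
#'
#' @param id Character vector of unique message ids.
#' @param text Character vector of message texts (nonempty).
#' @param source Character vector, each \code{"EXPERT"} or \code{"PEER"}.
#' @param stages List of character vectors (nonempty subsets of
#'   [readinessStages()]), or a character vector of \code{";"}-separated codes.
#' @param tags List of character vectors of content-tag labels (may be empty),
#'   or a \code{";"}-separated character vector.
#' @return A [MessageLibrary-class].
#' @examples
#' lib <- MessageLibrary(id = c("m1", "m2"),
#'                       text = c("You can do it", "Try the patch"),
#'                       source = c("PEER", "EXPERT"),
#'                       stages = list("THINKING", c("THINKING", "SET_QUIT_DATE")),
#'                       tags = list("MOTIVATIONAL_CONTENT", "BEHAVIORAL_TREATMENT"))
#' nMessages(lib)
#' @export
MessageLibrary <- function(id, text, source, stages, tags = vector("list", length(id))) {
  splitField <- function(x) {
    if (is.list(x)) return(lapply(x, as.character))
    lapply(strsplit(as.character(x), ";", fixed = TRUE), function(s) s[nzchar(trimws(s))])
  }
  tab <- data.frame(id = as.character(id), text = as.character(text),
                    source = toupper(as.character(source)),
                    stringsAsFactors = FALSE)
  tab$stages <- splitField(stages)
  tab$tags <- splitField(tags)
  mask <- vapply(tab$stages, function(s) readinessStages() %in% s,
                 logical(5))
  dim(mask) <- c(5L, nrow(tab))
  new("MessageLibrary", table = tab, stageMask = mask)
}

#' @describeIn MessageLibrary-class number of messages in the library
#' @param x A MessageLibrary.
#' @export
setMethod("nMessages", "MessageLibrary", function(x) nrow(x@table))

#' @describeIn MessageLibrary-class message ids, in library order
#' @export
setMethod("messageIds", "MessageLibrary", function(x) x@table$id)

#' @describeIn MessageLibrary-class number of messages (same as `nMessages`)
#' @export
setMethod("length", "MessageLibrary", function(x) nrow(x@table))

#' Message table accessor
#'
#' @param lib A [MessageLibrary-class].
#' @return The underlying \code{data.frame} (with list columns stages, tags).
#' @export
messageTable <- function(lib) {
  stopifnot(is(lib, "MessageLibrary"))
  lib@table
}

#' @describeIn MessageLibrary-class subset by index, id or logical mask
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "MessageLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@table$id)
  tab <- x@table[i, , drop = FALSE]
  rownames(tab) <- NULL
  new("MessageLibrary", table = tab,
      stageMask = x@stageMask[, i, drop = FALSE])
})

setMethod("show", "MessageLibrary", function(object) {
  tab <- object@table
  cat(sprintf("MessageLibrary with %d messages (%d expert, %d peer)\n",
              nrow(tab), sum(tab$source == "EXPERT"), sum(tab$source == "PEER")))
  if (nrow(tab)) {
    cnt <- vapply(readinessStages(), function(s)
      sum(vapply(tab$stages, function(st) s %in% st, logical(1))), integer(1))
    cat("  stage coverage:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
  }
})

#' Read a message library from a delimited text file
#'
#' Expects a header \code{id,text,source,stages,tags}; the list-valued
#' \code{stages} and \code{tags} columns use \code{";"} as the inner
#' separator. Malformed records and constraint violations (duplicate ids,
#' empty stage sets) are rejected with the offending line named.
#'
#' @param path Path to a CSV file.
#' @return A [MessageLibrary-class].
#' @seealso [writeMessageLibrary()]
#' @export
readMessageLibrary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(
    read.csv(path, colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("malformed message library file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("id", "text", "source", "stages", "tags")
  if (!all(need %in% names(tab)))
    stop("message library file lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup)) {
    lines <- which(tab$id %in% dup) + 1L  # +1 for the header line
    stop(sprintf("duplicate message id(s) %s (line %s)",
                 paste(dup, collapse = ", "),
                 paste(lines, collapse = ", ")), call. = FALSE)
  }
  empty <- which(!nzchar(trimws(tab$stages)))
  if (length(empty))
    stop(sprintf("empty stage set at line %s",
                 paste(empty + 1L, collapse = ", ")), call. = FALSE)
  MessageLibrary(tab$id, tab$text, tab$source, tab$stages, tab$tags)
}

#' Write a message library to a delimited text file
#'
#' Inverse of [readMessageLibrary()]: `read(write(lib))` is the identity on
#' all fields.
#'
#' @param lib A [MessageLibrary-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeMessageLibrary <- function(lib, path) {
  stopifnot(is(lib, "MessageLibrary"))
  tab <- lib@table
  out <- data.frame(id = tab$id, text = tab$text, source = tab$source,
                    stages = vapply(tab$stages, paste, character(1), collapse = ";"),
                    tags = vapply(tab$tags, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname filterByStage
#' @export
setMethod("filterByStage", "MessageLibrary", function(lib, stage) {
  if (length(stage) != 1L) stop("'stage' must be a single stage code")
  lib[lib@stageMask[stageIndex(stage), ]]
})

#' Tag prevalence across a message library
#'
#' Fraction of messages carrying each content tag, e.g. the audit that 40%
#' (102/261) of messages carry motivational content and 53% (139/261) describe
#' behavioral treatments.
#'
#' @param lib A nonempty [MessageLibrary-class].
#' @param tags Optional character vector of tags to report (defaults to every
#'   tag present); tags absent from the library report 0.
#' @return Named numeric vector of fractions in [0, 1].
#' @export
tagProportions <- function(lib, tags = NULL) {
  stopifnot(is(lib, "MessageLibrary"))
  n <- nMessages(lib)
  if (n == 0L) stop("tag proportions are undefined for an empty library", call. = FALSE)
  all <- unlist(lapply(lib@table$tags, unique))
  counts <- table(all)
  if (is.null(tags)) tags <- sort(names(counts))
  out <- as.numeric(counts[tags]) / n
  out[is.na(out)] <- 0
  names(out) <- tags
  out
}
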