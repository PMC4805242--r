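#' Construct an event matrix
#'
#' An `event_matrix` is the basic container of the package: an N x d numeric
#' matrix of fluorescence intensities, one row per cytometry event and one
#' column per channel, together with a tag recording which axis transform (if
#' any) has been applied.
#'
#' @param values Numeric matrix or data frame, N events x d channels.
#' @param channels Optional character vector of channel labels; defaults to
#'   the column names of `values`. Labels must be unique and non-empty.
#' @param transform_tag One of `"none"`, `"asinh"`, `"logicle"`.
#' @return An object of class `event_matrix`: the numeric matrix with unique
#'   column names and a `transform_tag` attribute.
#' @examples
#' em <- event_matrix(cbind(CD63 = rnorm(100), CD203c = rnorm(100)))
#' n_events(em)
#' channels(em)
#' @export
event_matrix <- function(values, channels = NULL,
                         transform_tag = c("none", "asinh", "logicle")) {
  transform_tag <- match.arg(transform_tag)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  if (is.null(channels)) channels <- colnames(values)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  channels <- as.character(channels)
  if (length(channels) != ncol(values))
    stop("length(channels) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(channels))
    stop("channel labels must be unique", call. = FALSE)
  if (nrow(values) < 1L)
    stop("degenerate input: event matrix must contain at least one event",
         call. = FALSE)
  if (ncol(values) < 1L)
    stop("event matrix must contain at least one channel", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("event matrix contains missing or non-finite values", call. = FALSE)
  colnames(values) <- channels
  rownames(values) <- NULL
  structure(values, transform_tag = transform_tag, class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d events x %d channels (transform: %s)\n",
              nrow(x), ncol(x), transform_tag(x)))
  cat("channels:", paste(channels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in an event matrix
#' @param events An `event_matrix`.
#' @return Integer event count.
#' @export
n_events <- function(events) nrow(events)

#' Channel labels of an event matrix
#' @param events An `event_matrix`.
#' @return Character vector of channel names.
#' @export
channels <- function(events) colnames(events)

#' Transform tag of an event matrix
#' @param events An `event_matrix`.
#' @return `"none"`, `"asinh"` or `"logicle"`.
#' @export
transform_tag <- function(events) {
  tag <- attr(events, "transform_tag")
  if (is.null(tag)) "none" else tag
}

as_event_matrix <- function(x) {
  if (inherits(x, "event_matrix")) return(x)
  event_matrix(x)
}

# Rebuild an event_matrix from a row subset, keeping tag and channels.
subset_events <- function(events, keep) {
  m <- events[keep, , drop = FALSE]
  if (nrow(m) < 1L)
    stop("degenerate input: 0 events survive (of ", nrow(events), ")",
         call. = FALSE)
  structure(m, transform_tag = transform_tag(events), class = "event_matrix")
}
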