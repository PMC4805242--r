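#' Build a probability-binning schema by recursive median splits
#'
#' Starting from all events, each node computes the per-channel sample
#' variance of its events, picks the channel with the largest variance (ties
#' broken toward the lower channel index), and splits the events at the
#' median of that channel into two equal halves (the first `ceiling(n/2)`
#' events in sorted order go left; the stored split value is the lower
#' median). Recursion continues while both children would still hold at
#' least `stop_threshold` events, producing hyper-rectangular bins with
#' (near-)equal occupancy — dense regions get many small bins, sparse
#' regions few large ones.
#'
#' @param events An [event_matrix()] with at least 2 events.
#' @param stop_threshold Minimum events per bin, or `"auto"` for `2 ln(N)`
#'   with `N` the total event count.
#' @return A `binning_schema`: the split tree plus bookkeeping
#'   (`n_leaves`, `stop_threshold`, `channels`).
#' @examples
#' em <- event_matrix(cbind(x = rnorm(1000)))
#' sch <- build_schema(em)
#' sch$n_leaves
#' @export
build_schema <- function(events, stop_threshold = "auto") {
  events <- as_event_matrix(events)
  n <- nrow(events)
  if (n < 2L)
    stop("degenerate input: need at least 2 events to build a schema",
         call. = FALSE)
  if (identical(stop_threshold, "auto")) stop_threshold <- 2 * log(n)
  if (!is.numeric(stop_threshold) || stop_threshold <= 0)
    stop("stop_threshold must be a positive number or \"auto\"",
         call. = FALSE)
  leaf_id <- 0L
  build <- function(idx) {
    m <- length(idx)
    vars <- if (m >= 2L) apply(events[idx, , drop = FALSE], 2L, stats::var)
            else rep(0, ncol(events))
    if (m < 2L || floor(m / 2) < stop_threshold || all(vars == 0)) {
      leaf_id <<- leaf_id + 1L
      return(list(leaf = TRUE, id = leaf_id, n_build = m))
    }
    dim <- unname(which.max(vars))  # ties -> lowest index
    v <- events[idx, dim]
    ord <- order(v)
    k <- ceiling(m / 2)
    split_value <- v[ord[k]]  # lower median
    list(leaf = FALSE, dim = dim, split = split_value,
         left = build(idx[ord[seq_len(k)]]),
         right = build(idx[ord[(k + 1L):m]]))
  }
  tree <- build(seq_len(n))
  if (isTRUE(tree$leaf) && floor(n / 2) >= stop_threshold)
    warning("all channels have zero variance: schema is a single bin",
            call. = FALSE)
  structure(list(tree = tree, n_leaves = leaf_id,
                 stop_threshold = stop_threshold, n_build = n,
                 channels = channels(events)),
            class = "binning_schema")
}

#' @export
print.binning_schema <- function(x, ...) {
  cat(sprintf("binning_schema: %d bins over %d channels (built on %d events, stop threshold %.2f)\n",
              x$n_leaves, length(x$channels), x$n_build, x$stop_threshold))
  invisible(x)
}

# Route each event down the comparison tree; value <= split goes left.
# Returns the leaf id of every event.
assign_bins <- function(events, schema) {
  events <- as_event_matrix(events)
  if (ncol(events) < length(schema$channels))
    stop("schema error: events have ", ncol(events),
         " channels, schema needs ", length(schema$channels), call. = FALSE)
  out <- integer(nrow(events))
  walk <- function(node, idx) {
    if (isTRUE(node$leaf)) { out[idx] <<- node$id; return(invisible()) }
    left <- events[idx, node$dim] <= node$split
    if (any(left)) walk(node$left, idx[left])
    if (any(!left)) walk(node$right, idx[!left])
  }
  walk(schema$tree, seq_len(nrow(events)))
  out
}

#' Bin a sample with a fixed schema
#'
#' Routes each event down the schema's comparison tree (channel value less
#' than or equal to the split goes left) and counts events per bin. Used to
#' bin a test sample with bins derived from a control sample, as the
#' probability-binning and chi-square statistics require.
#'
#' @param events An [event_matrix()].
#' @param schema A [build_schema()] result.
#' @return Integer vector of per-bin counts (length `schema$n_leaves`,
#'   summing to the event count).
#' @export
apply_schema <- function(events, schema) {
  if (!inherits(schema, "binning_schema"))
    stop("schema must be a binning_schema", call. = FALSE)
  ids <- assign_bins(events, schema)
  tabulate(ids, nbins = schema$n_leaves)
}

#' Construct a signature from centroids and weights
#'
#' A signature summarizes a distribution as bins, each carrying a centroid
#' (mean position of its events) and a weight (fraction of events).
#'
#' @param centroids Numeric matrix, one row per bin.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @return An object of class `emd_signature`.
#' @export
emd_signature <- function(centroids, weights) {
  if (!is.matrix(centroids)) centroids <- matrix(centroids, ncol = 1L)
  storage.mode(centroids) <- "double"
  weights <- as.numeric(weights)
  if (nrow(centroids) != length(weights))
    stop("one weight per centroid required", call. = FALSE)
  if (length(weights) < 1L) stop("signature needs at least one bin",
                                 call. = FALSE)
  if (any(weights < 0)) stop("signature weights must be non-negative",
                             call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("signature weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  structure(list(centroids = centroids, weights = weights),
            class = "emd_signature")
}

#' @export
print.emd_signature <- function(x, ...) {
  cat(sprintf("emd_signature: %d bins in %d dimension(s)\n",
              nrow(x$centroids), ncol(x$centroids)))
  invisible(x)
}

#' Number of bins in a signature
#' @param sig An [emd_signature()].
#' @return Integer bin count.
#' @export
n_bins <- function(sig) nrow(sig$centroids)

#' Summarize a sample as a signature
#'
#' Bins the events (building a schema from the sample itself when
#' `schema = "auto"`) and represents each non-empty bin by the mean of its
#' member events and the fraction of events it holds.
#'
#' @param events An [event_matrix()].
#' @param schema A [build_schema()] result, or `"auto"` to build one from
#'   `events`.
#' @param stop_threshold Passed to [build_schema()] when `schema = "auto"`.
#' @return An [emd_signature()]; weights sum to 1, empty bins are dropped.
#' @examples
#' em <- event_matrix(cbind(x = c(0, 0, 10, 10)))
#' compute_signature(em, stop_threshold = 2)
#' @export
compute_signature <- function(events, schema = "auto",
                              stop_threshold = "auto") {
  events <- as_event_matrix(events)
  if (identical(schema, "auto")) {
    if (nrow(events) == 1L)
      return(emd_signature(events[1L, , drop = FALSE], 1))
    schema <- build_schema(events, stop_threshold)
  }
  ids <- assign_bins(events, schema)
  counts <- tabulate(ids, nbins = schema$n_leaves)
  keep <- which(counts > 0L)
  d <- ncol(events)
  centroids <- matrix(0, length(keep), d,
                      dimnames = list(NULL, channels(events)))
  for (k in seq_along(keep))
    centroids[k, ] <- colMeans(events[ids == keep[k], , drop = FALSE])
  emd_signature(centroids, counts[keep] / nrow(events))
}

#' Serialize a binning schema to JSON
#' @param schema A `binning_schema`.
#' @return A JSON string (nested split objects).
#' @export
schema_to_json <- function(schema) {
  # 17 significant digits: split values round-trip bit-exactly, so routing
  # decisions (<= split) survive serialization
  jsonlite::toJSON(unclass(schema), auto_unbox = TRUE, digits = I(17))
}

#' Deserialize a binning schema from JSON
#' @param txt JSON string or path produced by [schema_to_json()].
#' @return A `binning_schema`.
#' @export
schema_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  structure(x, class = "binning_schema")
}

#' Serialize a signature to JSON
#' @param sig An [emd_signature()].
#' @return A JSON string with `centroids` (array of arrays) and `weights`.
#' @export
signature_to_json <- function(sig) {
  jsonlite::toJSON(list(centroids = sig$centroids, weights = sig$weights),
                   digits = I(17))
}

#' Deserialize a signature from JSON
#' @param txt JSON string or path produced by [signature_to_json()].
#' @return An [emd_signature()].
#' @export
signature_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  emd_signature(x$centroids, x$weights)
}
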