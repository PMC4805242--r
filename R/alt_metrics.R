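# Baseline measures the EMD workflow is compared against: the normalized
# probability-binning statistic, a symmetric chi-square over shared bins,
# the Mahalanobis distance between sample means, and per-channel MFI deltas.

binned_fractions <- function(control, test, schema) {
  control <- as_event_matrix(control); test <- as_event_matrix(test)
  if (identical(schema, "auto")) schema <- build_schema(control)
  if (!inherits(schema, "binning_schema"))
    stop("schema must be a binning_schema or \"auto\"", call. = FALSE)
  if (schema$n_leaves < 2L)
    stop("need at least 2 bins (schema has ", schema$n_leaves, ")",
         call. = FALSE)
  cc <- apply_schema(control, schema)
  ct <- apply_schema(test, schema)
  used <- cc + ct > 0  # bins empty in both samples carry no information
  list(fc = cc[used] / sum(cc), ft = ct[used] / sum(ct),
       n_bins = sum(used), n_control = sum(cc), n_test = sum(ct))
}

#' Symmetric chi-square divergence between binned samples
#'
#' Bins both samples with a schema derived from the control (or supplied)
#' and returns `sum_i (c_i - t_i)^2 / (c_i + t_i)` over the bin fractions
#' `c_i`, `t_i`, omitting bins empty in both samples. Symmetric in its
#' arguments; 0 for identical binned frequencies; bounded above by 2.
#'
#' @param control,test [event_matrix()] objects.
#' @param schema A [build_schema()] result or `"auto"` (build from
#'   `control`).
#' @return A single non-negative number.
#' @export
chi_square <- function(control, test, schema = "auto") {
  b <- binned_fractions(control, test, schema)
  sum((b$fc - b$ft)^2 / (b$fc + b$ft))
}

#' Probability-binning statistic T(chi)
#'
#' The symmetric binned chi-square, centered and scaled by its approximate
#' null moments so that two samples from the same distribution score near 0
#' with variance near 1. With `B` bins used and sample sizes `n_c`, `n_t`,
#' the chi-square of identical distributions has expectation approximately
#' `mu0 = (B - 1) (1/n_c + 1/n_t) / 2` and standard deviation
#' `sigma0 = sqrt(2 (B - 1)) (1/n_c + 1/n_t) / 2` (each bin contributes an
#' approximately scaled chi-square(1) term), so the statistic returned is
#' `(chi - mu0) / sigma0`, clipped at 0 (identical samples have `chi = 0`,
#' below the null mean, and the statistic is reported on a non-negative
#' scale). Because the chi-square is bounded above by 2, the statistic
#' plateaus once two distributions are fully separated: moving them further
#' apart adds no evidence. This p-value-style saturation is the behavior
#' the Earth Mover's Distance is designed to avoid.
#'
#' @inheritParams chi_square
#' @return A single non-negative number; near 0 under the null, large for
#'   separated distributions, bounded above for any fixed binning and
#'   sample sizes.
#' @export
pb_statistic <- function(control, test, schema = "auto") {
  b <- binned_fractions(control, test, schema)
  chi <- sum((b$fc - b$ft)^2 / (b$fc + b$ft))
  inv <- (1 / b$n_control + 1 / b$n_test) / 2
  mu0 <- (b$n_bins - 1) * inv
  sigma0 <- sqrt(2 * (b$n_bins - 1)) * inv
  max(0, (chi - mu0) / sigma0)
}

#' Mahalanobis distance between two samples
#'
#' Distance between the sample mean vectors in units of the pooled sample
#' covariance: `sqrt((mu_c - mu_t)' S^-1 (mu_c - mu_t))` with
#' `S = ((n_c - 1) S_c + (n_t - 1) S_t) / (n_c + n_t - 2)`.
#'
#' @param control,test [event_matrix()] objects on the same channels, each
#'   with at least `d + 1` events.
#' @param ridge Optional non-negative ridge added to the diagonal of `S`
#'   (default 0); use when the pooled covariance is singular.
#' @return A single non-negative number.
#' @export
mahalanobis_distance <- function(control, test, ridge = 0) {
  control <- as_event_matrix(control); test <- as_event_matrix(test)
  d <- ncol(control)
  if (ncol(test) != d) stop("samples differ in dimensionality",
                            call. = FALSE)
  if (nrow(control) < d + 1L || nrow(test) < d + 1L)
    stop("need at least d + 1 events per sample for a pooled covariance",
         call. = FALSE)
  nc <- nrow(control); nt <- nrow(test)
  S <- ((nc - 1) * stats::cov(control) + (nt - 1) * stats::cov(test)) /
    (nc + nt - 2)
  if (ridge > 0) S <- S + diag(ridge, d)
  delta <- colMeans(control) - colMeans(test)
  q <- tryCatch(stats::mahalanobis(matrix(delta, 1), rep(0, d), S),
                error = function(e)
                  stop("pooled covariance is singular; retry with a small ",
                       "ridge > 0", call. = FALSE))
  sqrt(as.numeric(q))
}

# lower median: order statistic ceiling(n/2), deterministic for even n
lower_median <- function(v) sort(v)[ceiling(length(v) / 2)]

#' Median fluorescence intensity difference on one channel
#'
#' Signed difference `median(test) - median(control)` of one channel's
#' intensities, the classical single-marker activation readout. The lower
#' median is used for even sample sizes so the value is always an observed
#' intensity.
#'
#' @param control,test [event_matrix()] objects.
#' @param channel Channel label present in both samples.
#' @return A single (signed) number.
#' @export
mfi_delta <- function(control, test, channel) {
  control <- as_event_matrix(control); test <- as_event_matrix(test)
  if (!channel %in% colnames(control) || !channel %in% colnames(test))
    stop("channel '", channel, "' missing from control or test",
         call. = FALSE)
  lower_median(test[, channel]) - lower_median(control[, channel])
}

#' Score one control/test sample pair with a named measure
#'
#' Uniform record for any of the supported comparison measures, suitable for
#' assembling classifier input tables.
#'
#' @param measure One of `"EMD"`, `"PB"`, `"ChS"`, `"MD"`, `"MFI_delta"`.
#' @param control,test [event_matrix()] objects (`control` is the reference,
#'   e.g. the unstimulated sample).
#' @param channels Channels entering the measure (for `"MFI_delta"`, exactly
#'   one).
#' @param control_id,test_id Sample identifiers carried into the record.
#' @param ... Extra arguments passed to the underlying measure.
#' @return A `comparison_score`: list with `measure`, `value`, `channels`,
#'   `control_id`, `test_id`.
#' @export
comparison_score <- function(measure = c("EMD", "PB", "ChS", "MD",
                                         "MFI_delta"),
                             control, test, channels = NULL,
                             control_id = "control", test_id = "test", ...) {
  measure <- match.arg(measure)
  control <- as_event_matrix(control); test <- as_event_matrix(test)
  if (is.null(channels)) channels <- colnames(control)
  cm <- subset_channels(control, channels)
  tm <- subset_channels(test, channels)
  value <- switch(measure,
    EMD = emd_events(cm, tm, ...),
    PB = pb_statistic(cm, tm, ...),
    ChS = chi_square(cm, tm, ...),
    MD = mahalanobis_distance(cm, tm, ...),
    MFI_delta = {
      if (length(channels) != 1L)
        stop("MFI_delta uses exactly one channel", call. = FALSE)
      mfi_delta(control, test, channels)
    })
  if (!is.finite(value)) stop("measure produced a non-finite value",
                              call. = FALSE)
  structure(list(measure = measure, value = value, channels = channels,
                 control_id = control_id, test_id = test_id),
            class = "comparison_score")
}

#' @export
print.comparison_score <- function(x, ...) {
  cat(sprintf("%s(%s, %s) on [%s] = %.6g\n", x$measure, x$control_id,
              x$test_id, paste(x$channels, collapse = ", "), x$value))
  invisible(x)
}

#' Serialize a comparison score to JSON
#' @param score A [comparison_score()].
#' @return A JSON string.
#' @export
score_to_json <- function(score) {
  jsonlite::toJSON(unclass(score), auto_unbox = TRUE, digits = NA)
}
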