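# Synthetic flow-cytometry-like data: Gaussian-mixture cell populations
# with controllable subset location/frequency, instrument-drift style
# translations, and paired control/stimulated cohorts with two responder
# classes. All generators are seed-deterministic.

#' Specify a Gaussian mixture of cell subpopulations
#'
#' @param means Numeric matrix, one row per component (k x d), or a vector
#'   for a single component.
#' @param sds Per-component, per-channel standard deviations (k x d matrix,
#'   vector recycled across components, or single number); channels are
#'   independent within a component.
#' @param weights Component weights summing to 1.
#' @param n Number of events to draw.
#' @param seed Integer seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @param channels Optional channel labels (default `ch1..chd`).
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(means, sds = 1, weights = 1, n = 1000L,
                         seed = NULL, channels = NULL) {
  if (!is.matrix(means)) means <- matrix(means, nrow = length(weights))
  k <- nrow(means); d <- ncol(means)
  if (!is.matrix(sds)) sds <- matrix(sds, k, d, byrow = length(sds) == d)
  if (any(sds < 0)) stop("invalid spec: SDs must be non-negative",
                         call. = FALSE)
  weights <- as.numeric(weights)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("invalid spec: weights must be non-negative and sum to 1",
         call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("invalid spec: n must be >= 1",
                               call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d))
  structure(list(means = means, sds = sds, weights = weights, n = n,
                 seed = seed, channels = channels), class = "mixture_spec")
}

#' Draw events from a Gaussian mixture
#'
#' Component membership counts are multinomial in the weights; each
#' component is an axis-aligned Gaussian. Event rows are shuffled so row
#' order carries no component information.
#'
#' @param spec A [mixture_spec()].
#' @return An [event_matrix()] with `spec$n` rows.
#' @examples
#' sp <- mixture_spec(means = rbind(0, 4), weights = c(0.8, 0.2),
#'                    n = 500, seed = 1)
#' sample_mixture(sp)
#' @export
sample_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  k <- nrow(spec$means); d <- ncol(spec$means)
  counts <- drop(stats::rmultinom(1L, spec$n, spec$weights))
  m <- matrix(0, spec$n, d, dimnames = list(NULL, spec$channels))
  row <- 0L
  for (comp in seq_len(k)) {
    nc <- counts[comp]
    if (nc == 0L) next
    block <- matrix(stats::rnorm(nc * d), nc, d)
    block <- sweep(block, 2L, spec$sds[comp, ], "*")
    block <- sweep(block, 2L, spec$means[comp, ], "+")
    m[row + seq_len(nc), ] <- block
    row <- row + nc
  }
  m <- m[sample.int(spec$n), , drop = FALSE]
  event_matrix(m, channels = spec$channels)
}

#' Generate a reference sample and a series of shifted-subset samples
#'
#' Emulates the classic separation experiment: the reference is a pure
#' standard normal population; each series member is a mixture in which a
#' minor subpopulation (fraction `minor_fraction`) has moved `s` standard
#' deviations away. As `s` grows, the mass that must be transported stays
#' `minor_fraction` while the distance grows like `s`, so the EMD to the
#' reference grows linearly with slope approaching `minor_fraction`,
#' whereas p-value-based statistics saturate.
#'
#' @param shifts Non-negative shifts `s`, in SD units.
#' @param minor_fraction Weight of the moving subpopulation (default 0.2).
#' @param n Events per sample (default 20000).
#' @param seed Integer seed.
#' @param channel Channel label (1D series).
#' @return List with `reference` (an [event_matrix()]), `shifts`, and
#'   `samples` (one `event_matrix` per shift).
#' @export
shift_series <- function(shifts, minor_fraction = 0.2, n = 20000L,
                         seed = NULL, channel = "marker") {
  if (any(shifts < 0)) stop("shifts must be non-negative", call. = FALSE)
  if (minor_fraction < 0 || minor_fraction > 1)
    stop("minor_fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ref <- sample_mixture(mixture_spec(0, 1, 1, n, seed = NULL,
                                     channels = channel))
  samples <- lapply(shifts, function(s) {
    sample_mixture(mixture_spec(rbind(0, s), 1,
                                c(1 - minor_fraction, minor_fraction), n,
                                seed = NULL, channels = channel))
  })
  list(reference = ref, shifts = as.numeric(shifts), samples = samples)
}

#' Generate a paired control/stimulated cohort with two responder classes
#'
#' Each subject contributes an unstimulated control sample and a stimulated
#' sample on two channels (emulating CD203c/CD63 readouts of a basophil
#' activation test). Non-responders' stimulated samples equal their controls
#' in distribution up to a nuisance drift translation (instrument drift is
#' applied to the stimulated samples of *both* classes); in responders a
#' subpopulation of fraction `minor_fraction` additionally shifts by
#' `effect` on both channels.
#'
#' @param n_per_class Subjects per class.
#' @param effect Responder subpopulation shift (SD units) on both channels.
#' @param minor_fraction Responding subpopulation fraction (default 0.2).
#' @param nuisance_drift Translation applied to every stimulated sample on
#'   both channels (default 0).
#' @param n_events Events per sample (default 2000).
#' @param seed Integer seed.
#' @param channels Two channel labels.
#' @return A list of subjects; each is a list with `subject`, `label`
#'   (`"responder"`/`"non_responder"`), `control` and `stimulated`
#'   [event_matrix()] objects.
#' @export
gen_cohort <- function(n_per_class, effect, minor_fraction = 0.2,
                       nuisance_drift = 0, n_events = 2000L, seed = NULL,
                       channels = c("CD203c", "CD63")) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  base_mean <- c(0, 0)
  subjects <- list()
  labels <- rep(c("non_responder", "responder"), each = n_per_class)
  for (i in seq_along(labels)) {
    control <- sample_mixture(mixture_spec(rbind(base_mean), 1, 1,
                                           n_events, seed = NULL,
                                           channels = channels))
    stim_mean <- base_mean + nuisance_drift
    if (labels[i] == "responder") {
      spec <- mixture_spec(rbind(stim_mean, stim_mean + effect), 1,
                           c(1 - minor_fraction, minor_fraction),
                           n_events, seed = NULL, channels = channels)
    } else {
      spec <- mixture_spec(rbind(stim_mean), 1, 1, n_events, seed = NULL,
                           channels = channels)
    }
    subjects[[i]] <- list(subject = sprintf("S%02d", i), label = labels[i],
                          control = control,
                          stimulated = sample_mixture(spec))
  }
  subjects
}

#' Score every subject of a cohort with one comparison measure
#'
#' Computes `measure(control, stimulated)` for each subject and assembles a
#' [scored_cohort()] ready for [fit_linear_svm()] /
#' [repeated_subsample_validate()].
#'
#' @param cohort Output of [gen_cohort()].
#' @param measure One of `"EMD"`, `"PB"`, `"ChS"`, `"MD"`, `"MFI_delta"`.
#' @param channels Channels entering the measure.
#' @param ... Passed to [comparison_score()].
#' @return A [scored_cohort()] with one score column named after the
#'   measure.
#' @export
score_cohort <- function(cohort, measure = "EMD", channels = NULL, ...) {
  vals <- vapply(cohort, function(su)
    comparison_score(measure, su$control, su$stimulated,
                     channels = channels, control_id = su$subject,
                     test_id = su$subject, ...)$value, numeric(1L))
  scores <- matrix(vals, ncol = 1L, dimnames = list(NULL, measure))
  scored_cohort(vapply(cohort, `[[`, character(1L), "subject"),
                vapply(cohort, `[[`, character(1L), "label"),
                scores)
}
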