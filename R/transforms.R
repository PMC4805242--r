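#' Transform event intensities to a display/analysis scale
#'
#' Applies a strictly monotone axis transform channel-wise. The default is
#' the inverse hyperbolic sine `asinh(x / cofactor)`, which is near-linear
#' around zero and logarithmic for large intensities; the Logicle
#' (biexponential) transform is available with explicit parameters.
#'
#' @param events An [event_matrix()] with `transform_tag = "none"`.
#' @param method `"asinh"` (default) or `"logicle"`.
#' @param channels Channels to transform; default all.
#' @param cofactor asinh cofactor (intensity units); default 150.
#' @param T,W,M,A Logicle parameters: `T` top-of-scale intensity, `W`
#'   linearization width in decades (`W >= 0`), `M` number of decades the
#'   full scale covers, `A` additional negative decades. Output is in
#'   decades, so `x = T` maps to `M + A`.
#' @return A new `event_matrix` with the tag set to the method.
#' @examples
#' em <- event_matrix(cbind(CD63 = c(0, 150, 1500)))
#' transform_events(em, "asinh", cofactor = 150)
#' @export
transform_events <- function(events, method = c("asinh", "logicle"),
                             channels = NULL, cofactor = 150,
                             T = 262144, W = 0.5, M = 4.5, A = 0) {
  method <- match.arg(method)
  events <- as_event_matrix(events)
  if (transform_tag(events) != "none")
    stop("events already carry transform '", transform_tag(events), "'",
         call. = FALSE)
  if (is.null(channels)) channels <- colnames(events)
  bad <- setdiff(channels, colnames(events))
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- unclass(events)
  attr(m, "transform_tag") <- NULL
  if (method == "asinh") {
    if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
      stop("invalid parameter: cofactor must be a positive scalar",
           call. = FALSE)
    m[, channels] <- asinh(m[, channels] / cofactor)
  } else {
    lg <- logicle_params(T = T, W = W, M = M, A = A)
    for (ch in channels) m[, ch] <- logicle_transform(m[, ch], lg)
  }
  event_matrix(m, transform_tag = method)
}

#' Precompute Logicle (biexponential) parameters
#'
#' The Logicle scale is the inverse of the biexponential
#' `B(y) = a e^(b y) - c e^(-d y) + f` on the normalized scale position
#' `y in [0, 1]`; the coefficients are derived from `(T, W, M, A)` so that
#' `B(1) = T`, the quasi-linear region has width `2 W` decades, and `B` has
#' zero slope-asymmetry at the center of that region. Returned scale values
#' are in decades (`(M + A) * y`).
#'
#' @inheritParams transform_events
#' @return A list of coefficients used by [logicle_transform()].
#' @export
logicle_params <- function(T = 262144, W = 0.5, M = 4.5, A = 0) {
  if (T <= 0 || M <= 0) stop("invalid parameter: T and M must be positive",
                             call. = FALSE)
  if (W < 0) stop("invalid parameter: W must be non-negative", call. = FALSE)
  if (2 * W + A > M)
    stop("invalid parameter: need 2W + A <= M", call. = FALSE)
  b <- (M + A) * log(10)
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  d <- if (w == 0) b else {
    # root of 2 (ln d - ln b) + w (b + d) = 0 on (0, b)
    stats::uniroot(function(dd) 2 * (log(dd) - log(b)) + w * (b + dd),
                   lower = b * 1e-12, upper = b, tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a <- T / (exp(b) - mf_a - c_a / exp(d))
  list(T = T, W = W, M = M, A = A, a = a, b = b, c = c_a * a, d = d,
       f = -mf_a * a, x1 = x1)
}

# biexponential B(y) on the normalized scale y
logicle_biexp <- function(y, p) {
  p$a * exp(p$b * y) - p$c * exp(-p$d * y) + p$f
}

#' Apply the Logicle transform to a numeric vector
#'
#' Inverts the biexponential numerically (vectorized bisection refined by
#' Newton steps); monotone to machine precision.
#'
#' @param x Raw intensities.
#' @param params Output of [logicle_params()].
#' @return Scale values in decades.
#' @export
logicle_transform <- function(x, params) {
  p <- params
  lo <- rep(-0.5, length(x)); hi <- rep(1.5, length(x))
  while (any(logicle_biexp(lo, p) > x)) lo[logicle_biexp(lo, p) > x] <- lo[logicle_biexp(lo, p) > x] - 0.5
  while (any(logicle_biexp(hi, p) < x)) hi[logicle_biexp(hi, p) < x] <- hi[logicle_biexp(hi, p) < x] + 0.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- logicle_biexp(mid, p) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (p$M + p$A) * (lo + hi) / 2
}
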