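#' Assemble a scored cohort for classification
#'
#' @param subject Character or integer subject identifiers (unique).
#' @param label Class labels; exactly two distinct values must be present.
#' @param scores Numeric vector (one score) or matrix/data frame (several
#'   measures) of per-subject comparison scores; no missing values.
#' @return A `scored_cohort`: list with `subject`, `label` (factor with two
#'   levels), `scores` (numeric matrix).
#' @export
scored_cohort <- function(subject, label, scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1L,
                                           dimnames = list(NULL, "score"))
  storage.mode(scores) <- "double"
  subject <- as.character(subject)
  if (anyDuplicated(subject)) stop("subject ids must be unique",
                                   call. = FALSE)
  if (length(subject) != nrow(scores) || length(label) != nrow(scores))
    stop("subject, label and scores must have one entry per subject",
         call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores contain missing or non-finite values", call. = FALSE)
  label <- factor(label)
  if (nlevels(label) != 2L)
    stop("exactly two class labels required (got ", nlevels(label), ")",
         call. = FALSE)
  structure(list(subject = subject, label = label, scores = scores),
            class = "scored_cohort")
}

#' Fit a linear maximum-margin separator on comparison scores
#'
#' Linear support vector machine on the raw score space (no feature
#' normalization). For one-dimensional, linearly separable scores with an
#' effectively hard margin the threshold is computed in closed form as the
#' midpoint between the closest opposing scores; otherwise the soft-margin
#' SVM is fit with \pkg{e1071} (libsvm). Points exactly on the separator are
#' assigned to the positive-side class.
#'
#' @param cohort A [scored_cohort()].
#' @param C Regularization parameter; large values (e.g. `1e5`) give a hard
#'   margin, `C = 1` a soft margin.
#' @return An `svm_separator`: list with weight vector `w`, offset `b`
#'   (decision value `w . x + b`), `threshold` (`-b/w`, 1D only), `classes`
#'   (negative-side, positive-side), and `C`.
#' @examples
#' co <- scored_cohort(1:4, c("A", "A", "B", "B"), c(1, 2, 5, 6))
#' fit_linear_svm(co, C = 1e5)$threshold  # 3.5
#' @export
fit_linear_svm <- function(cohort, C = 1e5) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(C) || C <= 0) stop("C must be positive", call. = FALSE)
  x <- cohort$scores
  y <- cohort$label
  if (any(table(y) == 0L))
    stop("both classes must be present in the training set", call. = FALSE)
  sep <- NULL
  if (ncol(x) == 1L) sep <- svm_1d_analytic(x[, 1L], y, C)
  if (is.null(sep)) sep <- svm_libsvm(x, y, C)
  sep$C <- C
  structure(sep, class = "svm_separator")
}

# closed-form hard-margin solution for separable 1D scores; returns NULL
# when the data are not separable or C is small enough to relax the margin
svm_1d_analytic <- function(v, y, C) {
  lv <- levels(y)
  a <- v[y == lv[1L]]; b <- v[y == lv[2L]]
  if (max(a) < min(b)) { lo <- max(a); hi <- min(b); pos <- lv[2L]; neg <- lv[1L] }
  else if (max(b) < min(a)) { lo <- max(b); hi <- min(a); pos <- lv[1L]; neg <- lv[2L] }
  else return(NULL)
  g <- hi - lo
  if (g <= 0 || C < 2 / g^2) return(NULL)  # soft margin would differ
  w <- 2 / g
  thr <- (lo + hi) / 2
  list(w = w, b = -w * thr, threshold = thr, classes = c(neg, pos))
}

svm_libsvm <- function(x, y, C) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the decision value: positive side = class with larger mean f
  f <- drop(x %*% w) + b
  means <- tapply(f, y, mean)
  pos <- names(which.max(means)); neg <- setdiff(levels(y), pos)
  list(w = w, b = b,
       threshold = if (length(w) == 1L && w != 0) unname(-b / w) else NA_real_,
       classes = c(neg, pos))
}

#' @export
print.svm_separator <- function(x, ...) {
  cat(sprintf("svm_separator: f(x) = w.x + b, C = %g; positive side -> '%s'\n",
              x$C, x$classes[2L]))
  if (!is.na(x$threshold[1L]))
    cat(sprintf("  1D threshold: %.6g\n", x$threshold))
  invisible(x)
}

#' Predict class labels with a fitted separator
#'
#' @param object An `svm_separator`.
#' @param newdata Numeric vector or matrix of scores.
#' @param ... Unused.
#' @return Character vector of predicted labels; decision values `>= 0` map
#'   to the positive-side class.
#' @export
predict.svm_separator <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata,
                                             ncol = length(object$w))
  f <- drop(newdata %*% object$w) + object$b
  ifelse(f >= 0, object$classes[2L], object$classes[1L])
}

count_errors <- function(sep, x, y) sum(predict(sep, x) != as.character(y))

#' Validate a score-based classifier by repeated sub-sampling
#'
#' Repeatedly splits the cohort into a training subset (`train_per_class`
#' subjects per class) and a held-out validation subset, fits the linear SVM
#' on the training subset and counts validation misclassifications.
#' `mode = "exhaustive"` evaluates every combination of training subjects;
#' `mode = "random"` draws `n_reps` random splits and then adds targeted
#' splits so that every subject is held out at least once. The headline
#' number is the minimum validation error over splits (the "best"
#' classification); the mean over splits is reported alongside because the
#' minimum is an optimistic summary.
#'
#' @param cohort A [scored_cohort()].
#' @param train_per_class Training subjects per class (must be smaller than
#'   the smaller class).
#' @param C SVM regularization parameter.
#' @param mode `"exhaustive"` or `"random"`.
#' @param n_reps Number of random splits (random mode).
#' @param seed Integer seed, required in random mode.
#' @param max_combinations Safety cap on exhaustive enumeration.
#' @return A `classifier_result`: list with `splits` (data frame: training
#'   and validation misclassification counts and holdout size per split),
#'   `best_val_error`, `mean_val_error`, `n_splits`, `separator` (fit on the
#'   full cohort), `holdout` (list of held-out subject indices per split),
#'   `predictions` (list of held-out predictions per split).
#' @export
repeated_subsample_validate <- function(cohort, train_per_class, C = 1e5,
                                        mode = c("exhaustive", "random"),
                                        n_reps = 200, seed = NULL,
                                        max_combinations = 1e5) {
  stopifnot(inherits(cohort, "scored_cohort"))
  mode <- match.arg(mode)
  y <- cohort$label
  idx1 <- which(y == levels(y)[1L]); idx2 <- which(y == levels(y)[2L])
  n1 <- length(idx1); n2 <- length(idx2)
  k <- as.integer(train_per_class)
  if (k < 1L || k >= n1 || k >= n2)
    stop("train_per_class must leave at least one held-out subject per class",
         call. = FALSE)
  if (mode == "exhaustive") {
    n_comb <- choose(n1, k) * choose(n2, k)
    if (n_comb > max_combinations)
      stop("exhaustive mode would evaluate ", n_comb,
           " splits (cap ", max_combinations, "); use mode = \"random\"",
           call. = FALSE)
    c1 <- utils::combn(idx1, k); c2 <- utils::combn(idx2, k)
    train_sets <- vector("list", n_comb)
    s <- 0L
    for (a in seq_len(ncol(c1))) for (b in seq_len(ncol(c2))) {
      s <- s + 1L
      train_sets[[s]] <- c(c1[, a], c2[, b])
    }
  } else {
    if (is.null(seed)) stop("seed is required in random mode", call. = FALSE)
    set.seed(as.integer(seed))
    train_sets <- replicate(n_reps,
                            c(sample(idx1, k), sample(idx2, k)),
                            simplify = FALSE)
    # coverage: every subject held out at least once
    held <- unique(unlist(lapply(train_sets, function(tr)
      setdiff(seq_along(y), tr))))
    for (miss in setdiff(seq_along(y), held)) {
      own <- if (miss %in% idx1) idx1 else idx2
      other <- if (miss %in% idx1) idx2 else idx1
      train_sets[[length(train_sets) + 1L]] <-
        c(sample(setdiff(own, miss), k), sample(other, k))
    }
  }

  n_splits <- length(train_sets)
  train_err <- val_err <- holdout_n <- integer(n_splits)
  holdout <- predictions <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    tr <- train_sets[[s]]
    va <- setdiff(seq_along(y), tr)
    sub <- scored_cohort(cohort$subject[tr], y[tr],
                         cohort$scores[tr, , drop = FALSE])
    sep <- fit_linear_svm(sub, C = C)
    train_err[s] <- count_errors(sep, cohort$scores[tr, , drop = FALSE],
                                 y[tr])
    pred <- predict(sep, cohort$scores[va, , drop = FALSE])
    val_err[s] <- sum(pred != as.character(y[va]))
    holdout_n[s] <- length(va)
    holdout[[s]] <- va
    predictions[[s]] <- pred
  }
  structure(list(
    splits = data.frame(split = seq_len(n_splits), train_error = train_err,
                        validation_error = val_err,
                        holdout_size = holdout_n),
    best_val_error = min(val_err),
    mean_val_error = mean(val_err / holdout_n),
    n_splits = n_splits,
    separator = fit_linear_svm(cohort, C = C),
    holdout = holdout, predictions = predictions,
    C = C, mode = mode, train_per_class = k),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("classifier_result: %d %s splits (train %d/class, C = %g)\n",
              x$n_splits, x$mode, x$train_per_class, x$C))
  cat(sprintf("  best validation error: %d/%d; mean error rate: %.3f\n",
              x$best_val_error, x$splits$holdout_size[1L], x$mean_val_error))
  invisible(x)
}

#' Serialize a classifier result to JSON (including per-split assignments)
#' @param result A `classifier_result`.
#' @return A JSON string.
#' @export
classifier_result_to_json <- function(result) {
  jsonlite::toJSON(list(
    n_splits = result$n_splits, mode = result$mode, C = result$C,
    train_per_class = result$train_per_class,
    best_val_error = result$best_val_error,
    mean_val_error = result$mean_val_error,
    separator = list(w = result$separator$w, b = result$separator$b,
                     threshold = result$separator$threshold,
                     classes = result$separator$classes),
    splits = result$splits,
    holdout = result$holdout,
    predictions = result$predictions), auto_unbox = TRUE, digits = NA)
}
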