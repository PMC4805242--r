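test_that("chi-square matches hand arithmetic on a two-bin case", {
  # control fractions (0.5, 0.5); test fractions (0.25, 0.75)
  control <- event_matrix(matrix(c(0, 0, 1, 1), ncol = 1))
  test <- event_matrix(matrix(c(0, 1, 1, 1), ncol = 1))
  sch <- build_schema(control, stop_threshold = 2)
  expect_equal(sch$n_leaves, 2L)
  # (0.25^2 / 0.75) + (0.25^2 / 1.25) = 1/12 + 1/20
  expect_equal(chi_square(control, test, sch), 1 / 12 + 1 / 20,
               tolerance = 1e-12)
  # symmetric form: swapping the samples under the same bins is identical
  expect_equal(chi_square(test, control, sch),
               chi_square(control, test, sch), tolerance = 1e-12)
  expect_equal(chi_square(control, control, sch), 0)
})

test_that("probability-binning statistic is 0 for identical samples and near 0 under the null", {
  set.seed(41)
  control <- event_matrix(cbind(m = rnorm(4000)))
  expect_equal(pb_statistic(control, control), 0)

  # null replicates: same distribution, fresh draws
  null_vals <- replicate(60, {
    a <- event_matrix(cbind(m = rnorm(1500)))
    b <- event_matrix(cbind(m = rnorm(1500)))
    pb_statistic(a, b)
  })
  sep <- pb_statistic(control,
                      event_matrix(cbind(m = rnorm(4000, 50))))
  expect_lt(mean(null_vals), 3)
  expect_gt(sep, 50 * mean(pmax(null_vals, 0.01)))
})

test_that("probability-binning statistic plateaus at full separation", {
  set.seed(42)
  control <- event_matrix(cbind(m = rnorm(3000)))
  sch <- build_schema(control)
  far <- event_matrix(cbind(m = rnorm(3000, 40)))
  farther <- event_matrix(unclass(far) + 40)
  # beyond the last split boundary the bin counts cannot change
  expect_equal(pb_statistic(control, farther, sch),
               pb_statistic(control, far, sch), tolerance = 1e-12)
})

test_that("binned statistics require at least two bins", {
  flat <- event_matrix(matrix(rep(1, 20), ncol = 1))
  other <- event_matrix(matrix(rnorm(20), ncol = 1))
  sch1 <- suppressWarnings(build_schema(flat))
  expect_error(chi_square(flat, other, sch1), "at least 2 bins")
  expect_error(pb_statistic(flat, other, sch1), "at least 2 bins")
})

test_that("Mahalanobis distance matches closed forms and whitening", {
  # 1D, unit pooled variance, means 0 and 2
  control <- event_matrix(matrix(c(-1, 0, 1), ncol = 1))
  test <- event_matrix(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(mahalanobis_distance(control, test), 2, tolerance = 1e-12)
  expect_equal(mahalanobis_distance(control, control), 0)

  # 2D correlated data: whiten with the pooled covariance eigendecomposition
  set.seed(43)
  z <- matrix(rnorm(400), 200, 2)
  L <- matrix(c(1, 0.8, 0, 0.6), 2, 2)
  a <- event_matrix(z[1:100, ] %*% t(L))
  b <- event_matrix(sweep(z[101:200, ] %*% t(L), 2, c(1, -0.5), "+"))
  S <- (99 * cov(unclass(a)) + 99 * cov(unclass(b))) / 198
  e <- eigen(S, symmetric = TRUE)
  Wm <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  delta <- colMeans(unclass(a)) - colMeans(unclass(b))
  expect_equal(mahalanobis_distance(a, b), sqrt(sum((Wm %*% delta)^2)),
               tolerance = 1e-10)
})

test_that("Mahalanobis distance flags singular covariances and offers a ridge", {
  a <- event_matrix(cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8)))
  b <- event_matrix(cbind(x = c(2, 3, 4, 5), y = c(4, 6, 8, 10)))
  expect_error(mahalanobis_distance(a, b), "ridge")
  expect_true(is.finite(mahalanobis_distance(a, b, ridge = 1e-6)))
  expect_error(mahalanobis_distance(event_matrix(cbind(1, 2)), b),
               "d \\+ 1")
})

test_that("MFI delta uses the lower median and reports signed shifts", {
  control <- event_matrix(cbind(m = c(0, 1, 2, 3)))
  expect_equal(mfi_delta(control, control, "m"), 0)
  shifted <- event_matrix(cbind(m = c(0, 1, 2, 3) + 10))
  expect_equal(mfi_delta(control, shifted, "m"), 10)
  expect_equal(mfi_delta(shifted, control, "m"), -10)
  # lower-median convention for even N: median of (5,6,7,8) is 6
  test <- event_matrix(cbind(m = c(5, 6, 7, 8)))
  expect_equal(mfi_delta(control, test, "m"), 6 - 1)
  expect_error(mfi_delta(control, test, "zz"), "missing")
})

test_that("comparison scores wrap every measure uniformly", {
  set.seed(44)
  a <- event_matrix(cbind(CD203c = rnorm(300), CD63 = rnorm(300)))
  b <- event_matrix(cbind(CD203c = rnorm(300, 1), CD63 = rnorm(300, 1)))
  for (m in c("EMD", "PB", "ChS", "MD")) {
    sc <- comparison_score(m, a, b, control_id = "c1", test_id = "p1")
    expect_s3_class(sc, "comparison_score")
    expect_equal(sc$measure, m)
    expect_true(is.finite(sc$value))
    expect_gte(sc$value, 0)
  }
  sc <- comparison_score("MFI_delta", a, b, channels = "CD63")
  expect_true(is.finite(sc$value))
  expect_error(comparison_score("MFI_delta", a, b), "exactly one channel")
  x <- jsonlite::fromJSON(score_to_json(
    comparison_score("EMD", a, b, control_id = "c1", test_id = "p1")))
  expect_equal(x$measure, "EMD")
  expect_equal(x$control_id, "c1")
})

test_that("all measures are non-negative and vanish on identical samples", {
  set.seed(45)
  a <- event_matrix(cbind(x = rnorm(500), y = rnorm(500)))
  sch <- build_schema(a)
  expect_equal(emd_events(a, a), 0, tolerance = 1e-12)
  expect_equal(chi_square(a, a, sch), 0)
  expect_equal(pb_statistic(a, a, sch), 0)
  expect_equal(mahalanobis_distance(a, a), 0)
  expect_equal(abs(mfi_delta(a, a, "x")), 0)
})
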