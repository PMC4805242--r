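test_that("delimited event tables parse with header channels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD63,CD203c", "1,2", "3,4", "5,6"), f)
  em <- read_events(f)
  expect_s3_class(em, "event_matrix")
  expect_equal(n_events(em), 3L)
  expect_equal(channels(em), c("CD63", "CD203c"))
  expect_equal(transform_tag(em), "none")
  expect_equal(unclass(em)[, "CD63"], c(1, 3, 5))

  ftab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), ftab)
  expect_equal(channels(read_events(ftab)), c("a", "b"))
})

test_that("degenerate and malformed inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_events(f), "empty")
  writeLines("CD63,CD203c", f) # header only, zero events
  expect_error(read_events(f), "no events")
  expect_error(read_events(file.path(tempdir(), "no-such-file.csv")),
               "no such file")
})

test_that("delimited write/read round-trips values", {
  set.seed(7)
  em <- event_matrix(matrix(rnorm(60), 20, 3,
                            dimnames = list(NULL, c("x", "y", "z"))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(em, f)
  back <- read_events(f)
  expect_equal(channels(back), channels(em))
  expect_equal(unclass(back), unclass(em), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("FCS files read back with correct events, channels and values", {
  set.seed(11)
  vals <- matrix(round(rnorm(100 * 4, 500, 100), 2), 100, 4)
  chans <- c("FSC-A", "SSC-A", "CD63", "CD203c")

  for (endian in c("little", "big")) {
    f <- withr::local_tempfile(fileext = ".fcs")
    write_fcs_fixture(f, vals, chans, datatype = "F", endian = endian)
    em <- read_events(f)
    expect_equal(n_events(em), 100L)
    expect_equal(channels(em), chans)
    expect_equal(unclass(em), vals, tolerance = 1e-5, ignore_attr = TRUE)
  }

  # 16-bit integer data, FCS2.0 header
  ivals <- matrix(sample.int(1024, 50 * 2, replace = TRUE), 50, 2)
  f2 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(f2, ivals, c("c1", "c2"), version = "FCS2.0",
                    datatype = "I")
  em2 <- read_events(f2, format = "fcs")
  expect_equal(unclass(em2), ivals + 0, ignore_attr = TRUE)

  # 64-bit double data
  f3 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(f3, vals[1:10, ], chans, datatype = "D")
  expect_equal(unclass(read_events(f3)), vals[1:10, ], ignore_attr = TRUE)
})

test_that("rectangular gating keeps closed-interval members in order", {
  em <- event_matrix(cbind(x = c(1, 5, 9)))
  g <- rect_gate(x = c(4, 10))
  expect_equal(as.vector(apply_gate(em, g)), c(5, 9))
  # boundary is inclusive
  expect_equal(as.vector(apply_gate(em, rect_gate(x = c(5, 9)))), c(5, 9))
  # whole-range gate is the identity
  expect_equal(unclass(apply_gate(em, rect_gate(x = c(0, 100)))),
               unclass(em), ignore_attr = TRUE)
})

test_that("2D gate on one channel leaves the other unconstrained", {
  set.seed(3)
  em <- event_matrix(cbind(a = runif(200, 0, 10), b = runif(200, 0, 10)))
  g <- rect_gate(a = c(2, 6))
  got <- apply_gate(em, g)
  keep <- em[, "a"] >= 2 & em[, "a"] <= 6 # brute-force membership
  expect_equal(unclass(got), unclass(em)[keep, ], ignore_attr = TRUE)
  # idempotence
  expect_equal(unclass(apply_gate(got, g)), unclass(got),
               ignore_attr = TRUE)
})

test_that("gate errors report surviving counts and unknown channels", {
  em <- event_matrix(cbind(x = c(1, 2, 3)))
  expect_error(apply_gate(em, rect_gate(x = c(10, 20))), "0 of 3")
  expect_error(apply_gate(em, rect_gate(y = c(0, 1))), "not present")
  expect_error(rect_gate(x = c(5, 1)), "lower <= upper")
})

test_that("asinh transform matches closed forms and sets the tag", {
  em <- event_matrix(cbind(m = c(0, 150, 1500)))
  t1 <- transform_events(em, "asinh", cofactor = 1)
  expect_equal(unname(t1[1, 1]), 0)
  t150 <- transform_events(em, "asinh", cofactor = 150)
  expect_equal(unname(t150[2, 1]), asinh(1), tolerance = 1e-12)
  expect_equal(transform_tag(t150), "asinh")
  expect_error(transform_events(t150, "asinh"), "already carry")
  expect_error(transform_events(em, "asinh", cofactor = -1), "positive")
})

test_that("logicle maps top-of-scale to full decades and zero to W", {
  p <- logicle_params(T = 262144, W = 0.5, M = 4.5, A = 0)
  # biexponential boundary: B(1) must equal T by construction
  expect_equal(flowEMD:::logicle_biexp(1, p), 262144, tolerance = 1e-6)
  expect_equal(logicle_transform(262144, p), 4.5, tolerance = 1e-9)
  # B(x1) = 0, and x1 corresponds to W decades when A = 0
  expect_equal(logicle_transform(0, p), 0.5, tolerance = 1e-9)
  expect_error(logicle_params(W = -0.1), "W must be non-negative")
})

test_that("transforms are strictly monotone per channel", {
  set.seed(5)
  x <- sort(runif(500, -2000, 262144))
  em <- event_matrix(cbind(m = sample(x)))
  for (method in c("asinh", "logicle")) {
    tr <- transform_events(em, method)
    expect_equal(order(tr[, 1]), order(em[, 1]))
    expect_true(all(diff(sort(tr[, 1])) > 0))
  }
})
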