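test_that("ground distances are plain Euclidean distances", {
  P <- emd_signature(matrix(c(0, 0), 1), 1)
  Q <- emd_signature(matrix(c(3, 4), 1), 1)
  expect_equal(ground_distance(P, Q)[1, 1], 5)

  set.seed(31)
  A <- rand_signature(3, 2)
  expect_equal(diag(ground_distance(A, A)), rep(0, 3))
  B <- rand_signature(4, 2)
  D <- ground_distance(A, B)
  for (i in 1:3) for (j in 1:4) # independent double-loop recomputation
    expect_equal(D[i, j],
                 sqrt(sum((A$centroids[i, ] - B$centroids[j, ])^2)),
                 tolerance = 1e-12)
  expect_error(ground_distance(A, rand_signature(2, 3)), "dimensionality")
})

test_that("the transport plan satisfies the marginal constraints", {
  set.seed(32)
  for (rep in 1:10) {
    P <- rand_signature(sample(2:8, 1), 2)
    Q <- rand_signature(sample(2:8, 1), 2)
    plan <- solve_transport(P, Q)
    expect_true(all(plan$flow >= 0))
    expect_equal(rowSums(plan$flow), P$weights, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(plan$flow), Q$weights, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(plan$flow), 1, tolerance = 1e-8)
    expect_equal(plan$emd, plan$cost, tolerance = 1e-12)
    expect_equal(sum(plan$flow * plan$ground), plan$cost,
                 tolerance = 1e-10)
  }
})

test_that("small transport problems solve to known optima", {
  # single route: all mass moves distance 3
  P <- emd_signature(matrix(0), 1)
  Q <- emd_signature(matrix(3), 1)
  plan <- solve_transport(P, Q)
  expect_equal(plan$flow[1, 1], 1)
  expect_equal(plan$cost, 3)

  # identical signatures: zero cost
  set.seed(33)
  R <- rand_signature(6, 3)
  expect_equal(solve_transport(R, R)$cost, 0, tolerance = 1e-12)

  # half the mass moves one unit
  P2 <- emd_signature(matrix(c(0, 1)), c(0.5, 0.5))
  Q2 <- emd_signature(matrix(c(0, 2)), c(0.5, 0.5))
  expect_equal(solve_transport(P2, Q2)$cost, 0.5, tolerance = 1e-12)
})

test_that("emd matches the independent simplex oracle on small instances", {
  set.seed(34)
  for (rep in 1:30) {
    P <- rand_signature(sample(1:5, 1), sample(1:3, 1))
    Q <- rand_signature(sample(1:5, 1), ncol(P$centroids))
    expect_equal(emd(P, Q), oracle_emd(P, Q), tolerance = 1e-8)
  }
})

test_that("emd is a metric: symmetry, identity, translation", {
  set.seed(35)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    P <- rand_signature(sample(2:7, 1), d)
    Q <- rand_signature(sample(2:7, 1), d)
    expect_gte(emd(P, Q), 0)
    expect_lt(abs(emd(P, Q) - emd(Q, P)), 1e-9)
    expect_equal(emd(P, P), 0, tolerance = 1e-12)
    v <- rnorm(d)
    # translating a signature against itself costs exactly the shift norm
    expect_equal(emd(P, shift_signature(P, v)), sqrt(sum(v^2)),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and invalid signatures are rejected", {
  P <- emd_signature(matrix(c(0, 1)), c(0.5, 0.5))
  # zero-weight bins are dropped before solving
  Qz <- emd_signature(matrix(c(0, 2, 50)), c(0.5, 0.5, 0))
  expect_equal(solve_transport(P, Qz)$cost, 0.5, tolerance = 1e-12)
  expect_equal(colSums(solve_transport(P, Qz)$flow)[3], 0,
               ignore_attr = TRUE)

  expect_error(emd_signature(matrix(c(0, 1)), c(0.5, 0.4)), "sum to 1")
  expect_error(emd_signature(matrix(c(0, 1)), c(1.5, -0.5)),
               "non-negative")
  # hand-built unnormalized signature: rejected unless normalize = TRUE
  bad <- structure(list(centroids = matrix(c(0, 2)), weights = c(1, 1)),
                   class = "emd_signature")
  expect_error(solve_transport(P, bad), "unit total mass")
  expect_equal(solve_transport(P, bad, normalize = TRUE)$cost, 0.5,
               tolerance = 1e-12)
})

test_that("the exact 1D distance integrates CDF differences", {
  expect_equal(emd_1d_exact(0, 3), 3)
  expect_equal(emd_1d_exact(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_1d_exact(c(0, 1), c(0, 2)), 0.5)
  expect_error(emd_1d_exact(numeric(0), 1), "non-empty")

  # equal sizes: mean absolute difference of matched order statistics
  set.seed(36)
  x <- rnorm(50); y <- rnorm(50, 1)
  expect_equal(emd_1d_exact(x, y), mean(abs(sort(x) - sort(y))),
               tolerance = 1e-12)
  # unequal sizes against point-mass signatures through the LP
  x2 <- rnorm(12); y2 <- rnorm(9)
  P <- emd_signature(matrix(x2), rep(1 / 12, 12))
  Q <- emd_signature(matrix(y2), rep(1 / 9, 9))
  expect_equal(emd_1d_exact(x2, y2), emd(P, Q), tolerance = 1e-10)
})

test_that("emd_events compares two raw samples end to end", {
  set.seed(37)
  a <- event_matrix(cbind(m = rnorm(2000)))
  b <- event_matrix(cbind(m = rnorm(2000, 1)))
  v <- emd_events(a, b)
  expect_gt(v, 0.7)
  expect_lt(v, 1.3)
  expect_equal(emd_events(a, a), 0, tolerance = 1e-12)
  expect_error(emd_events(a, event_matrix(cbind(z = rnorm(10)))),
               "missing")
})

test_that("transport results serialize to JSON", {
  P <- emd_signature(matrix(c(0, 1)), c(0.5, 0.5))
  Q <- emd_signature(matrix(c(0, 2)), c(0.5, 0.5))
  x <- jsonlite::fromJSON(plan_to_json(solve_transport(P, Q)))
  expect_equal(x$emd, 0.5)
  expect_equal(x$m, 2)
  expect_true(x$converged)
})
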