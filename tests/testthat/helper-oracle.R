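# Independent small-instance LP oracle: a dense two-phase tableau simplex
# with Bland's rule, used only to cross-check the package's transportation
# solver. Deliberately shares no code with the implementation under test.

# one simplex phase on a canonical tableau; Bland's rule throughout
simplex_core <- function(A, b, cost, basis, allowed, tol = 1e-11) {
  m <- nrow(A)
  repeat {
    cb <- cost[basis]
    red <- cost - drop(cb %*% A)
    red[basis] <- 0
    enter <- allowed[which(red[allowed] < -tol)]
    if (!length(enter)) break
    j <- min(enter) # Bland: smallest eligible index
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) stop("unbounded LP in oracle")
    ratio <- b[pos] / col[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    r <- cand[which.min(basis[cand])]
    piv <- A[r, j]
    A[r, ] <- A[r, ] / piv; b[r] <- b[r] / piv
    for (rr in seq_len(m)[-r]) {
      f <- A[rr, j]
      if (abs(f) > 0) { A[rr, ] <- A[rr, ] - f * A[r, ]; b[rr] <- b[rr] - f * b[r] }
    }
    basis[r] <- j
  }
  list(A = A, b = b, basis = basis, value = sum(cost[basis] * b))
}

# min cost'x  s.t.  A x = b, x >= 0
oracle_lp <- function(cost, A, b, tol = 1e-11) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, ]; b[flip] <- -b[flip]
  Ab <- cbind(A, diag(m))
  p1 <- simplex_core(Ab, b, c(rep(0, n), rep(1, m)),
                     basis = n + seq_len(m), allowed = seq_len(n + m), tol)
  if (p1$value > 1e-8) stop("infeasible LP in oracle")
  # pivot leftover zero-level artificials out where possible
  A2 <- p1$A; b2 <- p1$b; basis <- p1$basis
  for (r in which(basis > n)) {
    j <- which(abs(A2[r, seq_len(n)]) > tol)[1L]
    if (!is.na(j)) {
      piv <- A2[r, j]
      A2[r, ] <- A2[r, ] / piv; b2[r] <- b2[r] / piv
      for (rr in seq_len(m)[-r]) {
        f <- A2[rr, j]
        if (abs(f) > 0) { A2[rr, ] <- A2[rr, ] - f * A2[r, ]; b2[rr] <- b2[rr] - f * b2[r] }
      }
      basis[r] <- j
    }
  }
  p2 <- simplex_core(A2, b2, c(cost, rep(0, m)), basis,
                     allowed = seq_len(n), tol)
  x <- numeric(n)
  keep <- p2$basis <= n
  x[p2$basis[keep]] <- p2$b[keep]
  list(value = sum(cost * x), x = x)
}

# EMD via the generic oracle: variables f_ij column-major; constraints are
# the m row sums and the first n - 1 column sums (the last is redundant)
oracle_emd <- function(P, Q) {
  wp <- P$weights; wq <- Q$weights
  D <- as.matrix(stats::dist(rbind(P$centroids, Q$centroids)))
  m <- length(wp); n <- length(wq)
  D <- D[seq_len(m), m + seq_len(n), drop = FALSE]
  nv <- m * n
  A <- matrix(0, m + n - 1L, nv)
  for (i in seq_len(m)) A[i, i + m * (seq_len(n) - 1L)] <- 1
  for (j in seq_len(n - 1L)) A[m + j, m * (j - 1L) + seq_len(m)] <- 1
  res <- oracle_lp(as.vector(D), A, c(wp, wq[-n]))
  res$value
}

# random unit-mass signature for property tests
rand_signature <- function(k, d, spread = 3) {
  w <- stats::rexp(k) + 0.05
  emd_signature(matrix(stats::rnorm(k * d, sd = spread), k, d), w / sum(w))
}

shift_signature <- function(sig, v) {
  emd_signature(sweep(sig$centroids, 2L, v, "+"), sig$weights)
}
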