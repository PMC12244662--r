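# Independent oracles used across the suite.

# Double-loop per-entry covariance (columns as variables, unbiased).
covOracle <- function(M) {
  n <- nrow(M); p <- ncol(M)
  C <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    mi <- mean(M[, i]); mj <- mean(M[, j])
    C[i, j] <- sum((M[, i] - mi) * (M[, j] - mj)) / (n - 1)
  }
  C
}

# O(n^2) nondominance oracle: TRUE for rows no other row dominates.
nondomOracle <- function(F) {
  n <- nrow(F)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n)[-i], function(j)
      all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]), TRUE))
  }, TRUE)
}

# Monte-Carlo hypervolume estimate (2-D).
hvMonteCarlo <- function(A, ref, n = 1e6) {
  lo <- apply(A, 2L, min)
  x <- runif(n, lo[1L], ref[1L])
  y <- runif(n, lo[2L], ref[2L])
  dominated <- rep(FALSE, n)
  for (i in seq_len(nrow(A)))
    dominated <- dominated | (x >= A[i, 1L] & y >= A[i, 2L])
  mean(dominated) * prod(ref - lo)
}

# Inclusion-exclusion hypervolume oracle (any m, small n).
hvInclusionExclusion <- function(A, ref) {
  keep <- apply(A, 1L, function(p) all(p < ref))
  A <- A[keep, , drop = FALSE]
  n <- nrow(A)
  if (n == 0L) return(0)
  total <- 0
  for (sz in seq_len(n)) {
    combs <- utils::combn(n, sz)
    for (ci in seq_len(ncol(combs))) {
      corner <- apply(A[combs[, ci], , drop = FALSE], 2L, max)
      total <- total + (-1)^(sz + 1) * prod(ref - corner)
    }
  }
  total
}

# Extract the boundary pixels of a logical mask (4-neighbourhood).
maskBoundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up <- rbind(mask[1, ], mask[-h, ])
  dn <- rbind(mask[-1, ], mask[h, ])
  lf <- cbind(mask[, 1], mask[, -w])
  rt <- cbind(mask[, -1], mask[, w])
  mask & !(up & dn & lf & rt)
}

randomImage <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(h * w), h, w)
}
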