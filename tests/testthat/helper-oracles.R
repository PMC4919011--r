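# Independent oracles built from closed forms, deliberately avoiding the
# package's recursive/butterfly code paths.

# population count by string manipulation
oracle_pop <- function(i) {
  vapply(i, function(k) {
    sum(strsplit(paste(rev(as.integer(intToBits(k))), collapse = ""),
                 "")[[1]] == "1")
  }, numeric(1))
}

# Hadamard matrix from the closed form H[i, j] = (-1)^popcount(i & j)
oracle_H <- function(n) {
  idx <- 0:(2^n - 1)
  outer(idx, idx, function(i, j) (-1)^oracle_pop(bitwAnd(i, j)))
}

# interaction design from the subset test X[i, j] = 1 iff j subset of i
oracle_X <- function(n) {
  idx <- 0:(2^n - 1)
  outer(idx, idx, function(i, j) as.numeric(bitwAnd(i, j) == j))
}

# partial-averaging zero pattern from the OR-popcount rule
oracle_Z <- function(n, p) {
  idx <- 0:(2^n - 1)
  outer(idx, idx, function(i, j) as.numeric(oracle_pop(bitwOr(i, j)) <= p))
}

rand_landscape <- function(n, seed, with_sd = FALSE) {
  set.seed(seed)
  genotype_landscape(rnorm(2^n), n = n,
                     sd = if (with_sd) runif(2^n, 0.05, 0.3) else NULL)
}

# minimum-l1 solution of A x = b by vertex enumeration: every basic feasible
# solution uses at most nrow(A) linearly independent columns
oracle_min_l1 <- function(A, b, tol = 1e-9) {
  s <- nrow(A); N <- ncol(A)
  best <- NULL; best_l1 <- Inf
  for (k in 1:s) {
    for (cols in utils::combn(N, k, simplify = FALSE)) {
      As <- A[, cols, drop = FALSE]
      if (qr(As)$rank < length(cols)) next
      xs <- qr.coef(qr(As), b)
      if (max(abs(As %*% xs - b)) > tol) next
      x <- numeric(N); x[cols] <- xs
      if (sum(abs(x)) < best_l1 - 1e-12) {
        best_l1 <- sum(abs(x)); best <- x
      }
    }
  }
  best
}
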