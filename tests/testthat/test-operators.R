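test_that("Hadamard recursion matches the popcount closed form", {
  expect_equal(hadamard_matrix(1), rbind(c(1, 1), c(1, -1)),
               ignore_attr = TRUE)
  for (n in 1:8) {
    H <- hadamard_matrix(n)
    expect_equal(unname(H), unname(oracle_H(n)), ignore_attr = TRUE)
    expect_identical(H, t(H))
    expect_equal(H %*% H, 2^n * diag(2^n), ignore_attr = TRUE)
  }
})

test_that("mutant-cycle matrix is the exact integer inverse of the design", {
  expect_equal(mutant_cycle_matrix(1), rbind(c(1, 0), c(-1, 1)),
               ignore_attr = TRUE)
  for (n in 1:8) {
    G <- mutant_cycle_matrix(n)
    X <- interaction_design(n)
    expect_equal(unname(X), unname(oracle_X(n)), ignore_attr = TRUE)
    expect_true(all(G %in% c(-1L, 0L, 1L)))
    expect_true(all(diag(G) == 1L))
    expect_true(all(G[upper.tri(G)] == 0L))
    expect_identical(G %*% X, diag(2^n) + 0L * G)  # exact in integers
  }
})

test_that("averaging weights follow the (-1)^q / 2^(n-q) closed form", {
  for (n in c(2, 3, 5, 8)) {
    q <- genotype_order(0:(2^n - 1))
    expect_equal(diag(averaging_weights(n)), (-1)^q / 2^(n - q))
  }
  expect_equal(diag(averaging_weights(3))[1], 1 / 8)
  expect_equal(diag(averaging_weights(3))[8], -1)
})

test_that("mutant cycle is a weighted sub-sampling of the Hadamard transform", {
  for (n in 1:8) {
    G <- mutant_cycle_matrix(n)
    rhs <- averaging_weights(n) %*% t(interaction_design(n)) %*%
      hadamard_matrix(n)
    expect_equal(unname(rhs), unname(G) + 0, tolerance = 1e-12)
  }
})

test_that("order-truncation matrices keep the documented columns", {
  expect_equal(ncol(order_select(3, 2)), 7L)
  for (n in 2:6) for (r in 0:n) {
    Q <- order_select(n, r)
    expect_equal(ncol(Q), sum(choose(n, 0:r)))
    expect_equal(Q %*% t(Q), order_diag(n, r), ignore_attr = TRUE)
    kept <- apply(Q, 2, function(col) which(col == 1) - 1)
    expect_true(all(diff(kept) > 0))  # ascending genotype index
    expect_true(all(genotype_order(kept) <= r))
  }
  expect_error(order_select(3, 4), "in \\[0, n\\]")
})

test_that("partial-averaging recursion reproduces the OR-popcount rule", {
  for (n in 1:6) {
    expect_identical(partial_hadamard(n, n), hadamard_matrix(n))
    F0 <- partial_hadamard(n, 0)
    expect_equal(sum(F0 != 0), 1L)
    expect_equal(F0[1, 1], 1L)
    for (p in 0:n) {
      expect_equal(unname(partial_hadamard(n, p)),
                   unname(oracle_Z(n, p) * oracle_H(n)), ignore_attr = TRUE)
      expect_equal(unname(partial_mask(n, p)), unname(oracle_Z(n, p)),
                   ignore_attr = TRUE)
    }
  }
  # the row for genotype 001 at n=3, p=2 omits exactly the 110/111 columns
  Frow <- partial_hadamard(3, 2)[2, ]
  expect_equal(which(Frow == 0), c(7L, 8L))
})

test_that("partial weights use the background-count normaliser T(p, q)", {
  for (n in 2:6) for (p in 0:n) {
    q <- genotype_order(0:(2^n - 1))
    Tpq <- vapply(q, function(qq) sum(choose(n - qq, 0:(p - qq))), 1)
    w <- diag(partial_weights(n, p))
    expect_equal(w[q <= p], ((-1)^q / Tpq)[q <= p])
    expect_true(all(w[q > p] == 0))
  }
  # n=3, p=2, order-1 rows average over 3 backgrounds
  expect_equal(diag(partial_weights(3, 2))[2], -1 / 3)
})

test_that("mask matrix selects observed entries in ascending index order", {
  expect_equal(mask_matrix(rep(TRUE, 8)), diag(8), ignore_attr = TRUE)
  obs <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  M <- mask_matrix(obs)
  expect_equal(dim(M), c(4L, 8L))
  expect_equal(apply(M, 1, which.max), c(1, 2, 3, 5))
  set.seed(1)
  y <- rnorm(8)
  expect_equal(as.numeric(M %*% y), y[obs])
  expect_error(mask_matrix(rep(FALSE, 4)), "at least one")
})

test_that("matrix-free transforms agree with their dense operators", {
  for (n in c(1, 3, 6, 10)) {
    set.seed(n)
    y <- rnorm(2^n)
    if (n <= 8) {
      expect_equal(fast_wht(y), as.numeric(oracle_H(n) %*% y))
      expect_equal(subset_zeta(y), as.numeric(oracle_X(n) %*% y))
      expect_equal(superset_sum(y), as.numeric(t(oracle_X(n)) %*% y))
      expect_equal(subset_mobius(y),
                   as.numeric(solve(oracle_X(n)) %*% y))
    } else {
      expect_equal(fast_wht(y), as.numeric(hadamard_matrix(n) %*% y))
    }
    expect_equal(fast_wht(fast_wht(y)), 2^n * y)
    expect_equal(subset_zeta(subset_mobius(y)), y)
  }
  expect_equal(fast_wht(rep(2, 8)), c(16, rep(0, 7)))
  expect_error(fast_wht(rnorm(6)), "power of two")
})

test_that("dense construction refuses sizes beyond the documented cap", {
  expect_error(hadamard_matrix(15), "matrix-free")
  expect_error(epistasis_operator("background", 15), "matrix-free")
})
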