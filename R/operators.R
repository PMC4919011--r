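## Operator matrices on the Boolean hypercube.
##
## All operators share one indexing convention: row/column i (1-based in R)
## corresponds to genotype index i - 1, whose bitstring prints site n first.
## The recursions are carried out in integer arithmetic so that the algebraic
## identities between operators hold bit-exactly; weights (which are dyadic
## rationals) are applied in floating point afterwards.

## dense matrices above this size are refused
.DENSE_N_MAX <- 14L

.check_dense_n <- function(n) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be nonnegative")
  if (n > .DENSE_N_MAX)
    stop("dense operator matrices are limited to n <= ", .DENSE_N_MAX,
         "; use the matrix-free transforms (fast_wht, subset_zeta, ...)")
  n
}

#' Walsh-Hadamard and related operator matrices
#'
#' Dense constructors for the linear operators used to decompose a phenotype
#' landscape into interaction coefficients.  All follow block recursions in
#' the number of sites `n`:
#'
#' * `hadamard_matrix(n)`: the `2^n` by `2^n` Walsh-Hadamard matrix `H`,
#'   `H[i, j] = (-1)^popcount((i-1) & (j-1))`, symmetric with
#'   `H %*% H = 2^n I`.  Its rows are the Fourier basis functions of the
#'   Boolean hypercube.
#' * `averaging_weights(n)`: the diagonal weight matrix `V` with entries
#'   `(-1)^q / 2^(n-q)` at a row of interaction order `q`, normalising each
#'   Hadamard row by the number of genotype backgrounds averaged over.  The
#'   background-averaged spectrum is `V %*% H %*% y`.
#' * `mutant_cycle_matrix(n)`: the lower-triangular matrix `G` mapping
#'   phenotypes to reference-based (mutant-cycle) interaction terms of all
#'   orders; entries in `{-1, 0, 1}` with unit diagonal, equal to the Moebius
#'   (inclusion-exclusion) transform of the subset lattice.
#' * `interaction_design(n)`: the 0/1 design matrix `X` of the full-order
#'   interaction regression: `X[i, j] = 1` iff bitmask `j-1` is a subset of
#'   bitmask `i-1`.  `X` is the exact inverse of `G`.
#'
#' @param n number of sites (dense construction limited to `n <= 14`).
#' @return a base `matrix` of dimension `2^n` by `2^n`.
#' @examples
#' hadamard_matrix(2)
#' all(mutant_cycle_matrix(3) == solve(interaction_design(3)))
#' @seealso [order_select()], [partial_hadamard()], [fast_wht()]
#' @export
hadamard_matrix <- function(n) {
  n <- .check_dense_n(n)
  H <- matrix(1L, 1L, 1L)
  for (k in seq_len(n)) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' @rdname hadamard_matrix
#' @export
mutant_cycle_matrix <- function(n) {
  n <- .check_dense_n(n)
  G <- matrix(1L, 1L, 1L)
  for (k in seq_len(n)) {
    Z <- matrix(0L, nrow(G), ncol(G))
    G <- rbind(cbind(G, Z), cbind(-G, G))
  }
  G
}

#' @rdname hadamard_matrix
#' @export
interaction_design <- function(n) {
  n <- .check_dense_n(n)
  X <- matrix(1L, 1L, 1L)
  for (k in seq_len(n)) {
    Z <- matrix(0L, nrow(X), ncol(X))
    X <- rbind(cbind(X, Z), cbind(X, X))
  }
  X
}

#' @rdname hadamard_matrix
#' @export
averaging_weights <- function(n) {
  n <- .check_dense_n(n)
  q <- genotype_order(0:(2^n - 1L))
  diag((-1)^q / 2^(n - q), 2^n)
}

#' Order-truncation matrices for interaction regression
#'
#' `order_select(n, r)` is the `2^n` by `m` column-selection matrix `Q`
#' keeping the identity columns whose genotype index has order at most `r`;
#' `m = sum(choose(n, 0:r))`.  Retained columns appear in ascending genotype
#' index.  `order_diag(n, r)` is the diagonal 0/1 matrix `S = Q %*% t(Q)`
#' zeroing coefficients of order above `r`.
#'
#' @param n number of sites.
#' @param r highest interaction order retained (`0 <= r <= n`).
#' @return a base `matrix`.
#' @export
order_select <- function(n, r) {
  n <- .check_dense_n(n)
  if (r < 0 || r > n) stop("order r must be in [0, n]")
  keep <- genotype_order(0:(2^n - 1L)) <= r
  diag(2^n)[, keep, drop = FALSE]
}

#' @rdname order_select
#' @export
order_diag <- function(n, r) {
  n <- .check_dense_n(n)
  if (r < 0 || r > n) stop("order r must be in [0, n]")
  diag(as.numeric(genotype_order(0:(2^n - 1L)) <= r), 2^n)
}

#' Partial background-averaging operators
#'
#' For data complete only up to mutation order `p`, background averages are
#' taken over the observed backgrounds only.  `partial_hadamard(n, p)` builds
#' `F = Z * H` (element-wise product) by its block recursion in `n` and `p`,
#' with `F = H` for `n <= p` and, at `p = 0`, a single 1 in the top-left
#' corner.  `partial_mask(n, p)` is the 0/1 matrix `Z` zeroing Hadamard
#' entries that involve genotypes above order `p`; it satisfies
#' `Z[i, j] = 1` iff `popcount((i-1) | (j-1)) <= p` and displays the
#' Sierpinski-like self-similar pattern of the subset lattice.
#' `partial_weights(n, p)` is the diagonal matrix `W` with entries
#' `(-1)^q / T(p, q)` where `T(p, q) = sum(choose(n - q, 0:(p - q)))` counts
#' the backgrounds of order compatible with the data; rows of order `q > p`
#' are zero (those coefficients are not estimable).  The partial
#' background-averaged spectrum is `W %*% (Z * H) %*% y`.
#'
#' @param n number of sites.
#' @param p highest complete mutation order (`0 <= p <= n`).
#' @return a base `matrix` of dimension `2^n` by `2^n`.
#' @export
partial_hadamard <- function(n, p) {
  n <- .check_dense_n(n)
  if (p < 0 || p > n) stop("order p must be in [0, n]")
  if (n <= p) return(hadamard_matrix(n))
  if (p == 0L) {
    F0 <- matrix(0L, 2^n, 2^n); F0[1L, 1L] <- 1L
    return(F0)
  }
  A <- partial_hadamard(n - 1L, p)
  B <- partial_hadamard(n - 1L, p - 1L)
  rbind(cbind(A, B), cbind(B, -B))
}

#' @rdname partial_hadamard
#' @export
partial_mask <- function(n, p) {
  n <- .check_dense_n(n)
  if (p < 0 || p > n) stop("order p must be in [0, n]")
  idx <- 0:(2^n - 1L)
  ors <- outer(idx, idx, bitwOr)
  matrix(as.integer(genotype_order(c(ors)) <= p), 2^n, 2^n)
}

#' @rdname partial_hadamard
#' @export
partial_weights <- function(n, p) {
  n <- .check_dense_n(n)
  if (p < 0 || p > n) stop("order p must be in [0, n]")
  q <- genotype_order(0:(2^n - 1L))
  w <- ifelse(q <= p,
              (-1)^q / vapply(q, function(qq) sum(choose(n - qq, 0:(p - qq))), 1),
              0)
  diag(w, 2^n)
}

#' Row-selection matrix for observed genotypes
#'
#' Builds the `s` by `2^n` matrix `M` that picks the observed entries of a
#' phenotype vector, i.e. the identity matrix with the rows of unobserved
#' genotypes deleted; rows are kept in ascending genotype index.
#'
#' @param observed logical vector of length `2^n`, or a
#'   [genotype_landscape] whose `observed` field is used.
#' @return an `s` by `2^n` 0/1 matrix with one 1 per row.
#' @export
mask_matrix <- function(observed) {
  if (inherits(observed, "genotype_landscape")) observed <- observed$observed
  observed <- as.logical(observed)
  if (!any(observed)) stop("mask must select at least one genotype")
  if (2^round(log2(length(observed))) != length(observed))
    stop("mask length must be a power of two")
  diag(length(observed))[observed, , drop = FALSE]
}

#' The epistasis operator of a formalism
#'
#' Returns the dense linear operator mapping the complete phenotype vector to
#' the interaction coefficients of the chosen formalism:
#' `V %*% H` for background averaging, `G = V %*% t(X) %*% H` for the
#' mutant cycle, `V %*% t(X) %*% S %*% H` for regression truncated to order
#' `r` (a matrix-product route to the least-squares solution that requires no
#' matrix inversion), and `W %*% (Z * H)` for partial background averaging up
#' to order `p`.
#'
#' @param formalism one of `"background"`, `"cycle"`, `"regression"`,
#'   `"partial"`.
#' @param n number of sites.
#' @param order truncation order `r` (regression; default `n`) or complete
#'   order `p` (partial; required).
#' @return a `2^n` by `2^n` matrix.
#' @examples
#' # order-1 regression coefficients of an additive landscape
#' epistasis_operator("regression", 2, order = 1) %*% c(0, 1, 2, 3)
#' @export
epistasis_operator <- function(formalism = c("background", "cycle",
                                             "regression", "partial"),
                               n, order = NULL) {
  formalism <- match.arg(formalism)
  n <- .check_dense_n(n)
  switch(formalism,
    background = averaging_weights(n) %*% hadamard_matrix(n),
    cycle = {
      G <- mutant_cycle_matrix(n)
      storage.mode(G) <- "double"
      G
    },
    regression = {
      r <- if (is.null(order)) n else order
      averaging_weights(n) %*% t(interaction_design(n)) %*%
        order_diag(n, r) %*% hadamard_matrix(n)
    },
    partial = {
      if (is.null(order)) stop("partial averaging requires 'order' (p)")
      partial_weights(n, order) %*% partial_hadamard(n, order)
    })
}

#' Matrix-free transforms on the hypercube
#'
#' In-place butterfly algorithms running in `n * 2^n` operations, equivalent
#' to multiplication by the dense operators but usable far beyond the dense
#' size limit:
#'
#' * `fast_wht(y)`: the Walsh-Hadamard transform, `hadamard_matrix(n) %*% y`.
#'   Applying it twice returns `2^n * y`.
#' * `subset_zeta(y)`: subset sums, `interaction_design(n) %*% y`
#'   (`out[i] = sum over subsets j of i`).
#' * `subset_mobius(y)`: the inverse of `subset_zeta`,
#'   `mutant_cycle_matrix(n) %*% y` (signed inclusion-exclusion over
#'   subsets); this is the mutant-cycle decomposition itself.
#' * `superset_sum(y)`: `t(interaction_design(n)) %*% y`
#'   (`out[i] = sum over supersets j of i`).
#'
#' @param y numeric vector whose length is a power of two.
#' @return numeric vector of the same length.
#' @examples
#' y <- rnorm(8)
#' all.equal(fast_wht(y), c(hadamard_matrix(3) %*% y))
#' @export
fast_wht <- function(y) {
  n <- .pow2_n(y)
  h <- 1L
  while (h < length(y)) {
    for (s in seq(1L, length(y), by = 2L * h)) {
      i <- s:(s + h - 1L)
      a <- y[i]; b <- y[i + h]
      y[i] <- a + b; y[i + h] <- a - b
    }
    h <- 2L * h
  }
  y
}

#' @rdname fast_wht
#' @export
subset_zeta <- function(y) {
  n <- .pow2_n(y)
  h <- 1L
  while (h < length(y)) {
    for (s in seq(1L, length(y), by = 2L * h)) {
      i <- s:(s + h - 1L)
      y[i + h] <- y[i + h] + y[i]
    }
    h <- 2L * h
  }
  y
}

#' @rdname fast_wht
#' @export
subset_mobius <- function(y) {
  n <- .pow2_n(y)
  h <- 1L
  while (h < length(y)) {
    for (s in seq(1L, length(y), by = 2L * h)) {
      i <- s:(s + h - 1L)
      y[i + h] <- y[i + h] - y[i]
    }
    h <- 2L * h
  }
  y
}

#' @rdname fast_wht
#' @export
superset_sum <- function(y) {
  n <- .pow2_n(y)
  h <- 1L
  while (h < length(y)) {
    for (s in seq(1L, length(y), by = 2L * h)) {
      i <- s:(s + h - 1L)
      y[i] <- y[i] + y[i + h]
    }
    h <- 2L * h
  }
  y
}

.pow2_n <- function(y) {
  n <- round(log2(length(y)))
  if (2^n != length(y)) stop("length must be a power of two")
  as.integer(n)
}
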