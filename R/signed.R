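#' Signed-genotype encoding and its link to background averaging
#'
#' Re-encoding genotypes as `sigma = -1` (wild-type) / `+1` (mutant) and
#' regressing the phenotypes on all products of `sigma` over site subsets
#' gives a full-order polynomial fit whose coefficients are, order by order,
#' proportional to the background-averaged spectrum: the expected
#' proportionality factor at order `q` is `2^q` (Fourier versus Taylor
#' expansions of the same landscape).  This function performs the signed
#' full-order fit, computes the background-averaged spectrum, and reports
#' the per-order ratios.
#'
#' @param x a complete [genotype_landscape].
#' @param tol coefficients below `tol` in absolute value are excluded from
#'   ratio estimation (the ratio of two near-zero numbers is noise).
#' @return a list with `beta_signed` (signed-encoding coefficients),
#'   `epsilon` (background-averaged coefficients), `ratio_by_order` (mean
#'   observed ratio `epsilon / beta_signed` per order), `expected_ratio`
#'   (`2^q`), and `consistent` (all observed ratios within `1e-8` of the
#'   expected value).
#' @examples
#' sc <- signed_encoding(pdz_binding())
#' sc$ratio_by_order   # 1 2 4 8 for n = 3
#' @export
signed_encoding <- function(x, tol = 1e-10) {
  stopifnot(inherits(x, "genotype_landscape"))
  .require_complete(x, "signed encoding")
  n <- x$n
  idx <- 0:(2^n - 1L)
  q <- genotype_order(idx)
  ## design column j = product of sigma over the sites in bitmask j:
  ## entry (i, j) = (-1)^popcount(j & ~i)
  Xs <- outer(idx, idx, function(i, j)
    (-1)^genotype_order(bitwAnd(j, bitwAnd(bitwNot(i), 2^n - 1L))))
  beta_s <- solve(Xs, x$phenotype)
  eps <- coef(epistasis(x, "background"))
  ords <- sort(unique(q))
  ratio <- vapply(ords, function(k) {
    i <- q == k & abs(beta_s) > tol
    if (!any(i)) return(2^k)  # no informative term: ratio unobservable
    mean(eps[i] / beta_s[i])
  }, numeric(1))
  names(ratio) <- ords
  dev <- vapply(ords, function(k) {
    i <- q == k & abs(beta_s) > tol
    if (!any(i)) return(0)
    max(abs(eps[i] / beta_s[i] - 2^k))
  }, numeric(1))
  list(beta_signed = beta_s, epsilon = unname(eps),
       ratio_by_order = ratio, expected_ratio = 2^ords,
       consistent = all(dev < 1e-8))
}
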