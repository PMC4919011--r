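#' Decompose a genotype-phenotype landscape into epistatic coefficients
#'
#' Fits one of the linked interaction formalisms to a binary
#' genotype-phenotype landscape.  All four are weighted forms of the
#' Walsh-Hadamard transform of the phenotype vector `y`:
#'
#' * `"cycle"` -- mutant-cycle (reference-based, biochemical) epistasis:
#'   `lambda = G y`, the hierarchy of coupling terms relative to the
#'   all-wild-type genotype.  The order-0 term is the reference phenotype,
#'   order-1 terms are single-mutant effects, order-2 terms are coupling
#'   (double-mutant-cycle) energies, and so on.  Requires complete data.
#' * `"background"` -- background-averaged (ensemble) epistasis:
#'   `epsilon = V H y`, each interaction averaged over all genotypic states
#'   of the remaining sites.  The order-0 term is the grand mean; the
#'   highest-order term always equals its mutant-cycle counterpart (a single
#'   background).  Requires complete data.
#' * `"regression"` -- least-squares interaction regression truncated to
#'   order `r`: coefficients of the 0/1 interaction design up to order `r`.
#'   With complete data and `r = n` this reproduces the mutant cycle exactly
#'   with zero residuals; the retained coefficients at order `r` itself equal
#'   the corresponding background-averaged terms.  Works on incomplete data
#'   provided the observed design has full column rank (at least
#'   `sum(choose(n, 0:r))` informative genotypes); two mutations that always
#'   co-occur make the fit non-identifiable and raise an error.
#' * `"partial"` -- partial background averaging for data complete up to
#'   mutation order `p`: each interaction of order `q <= p` averaged over the
#'   `T(p, q)` observed backgrounds only.  Genotypes above order `p` are
#'   never read; coefficients above order `p` are returned as `NA`.
#'
#' When the landscape carries per-genotype standard deviations, coefficient
#' standard deviations are propagated through the operator rows as
#' `sd_i = sqrt(sum_j W_ij^2 sd_j^2)` (independent Gaussian measurement
#' errors).
#'
#' @param x a [genotype_landscape] (or a numeric phenotype vector of length
#'   `2^n`, converted via [genotype_landscape()]).
#' @param formalism one of `"background"`, `"cycle"`, `"regression"`,
#'   `"partial"`.
#' @param order truncation order: `r` for `"regression"` (default `n`, the
#'   full-order fit) or `p` for `"partial"` (default: the highest order up to
#'   which the data are complete).  Ignored otherwise.
#' @param method for `"regression"` on complete data: `"qr"` solves the
#'   least-squares problem by rank-revealing QR; `"operator"` evaluates the
#'   equivalent operator product `V t(X) S H y`, which needs no matrix
#'   factorisation.  Incomplete data always use `"qr"`.
#' @return An object of class `"epistasis"`: coefficients indexed by
#'   genotype bitmask and labelled in star notation (`"1*1"` = coupling of
#'   sites 3 and 1), with per-coefficient interaction `order`, propagated
#'   `sd` (when input errors are available), `residuals` and `rank_ok` for
#'   regression fits, and the input landscape.  Supports [coef()],
#'   [summary()], [predict()], [fitted()], [residuals()], [plot()] and
#'   [simulate()].
#' @examples
#' pdz <- pdz_binding()
#' fit <- epistasis(pdz, "cycle")
#' coef(fit)["111"]        # three-way coupling free energy
#' summary(epistasis(pdz, "background"))
#'
#' # order-2 regression: the triple-interaction term is structurally zero
#' epistasis(pdz, "regression", order = 2)
#' @references Standard notation: `H` Walsh-Hadamard matrix, `V`/`W` diagonal
#'   averaging weights, `X` interaction design, `G = X^-1` mutant-cycle
#'   operator, `Q`/`S` order truncation, `M` observation mask.
#' @export
epistasis <- function(x, formalism = c("background", "cycle",
                                       "regression", "partial"),
                      order = NULL, method = c("qr", "operator")) {
  formalism <- match.arg(formalism)
  method <- match.arg(method)
  if (!inherits(x, "genotype_landscape")) x <- genotype_landscape(x)
  cl <- match.call()
  fit <- switch(formalism,
    cycle = .fit_cycle(x),
    background = .fit_background(x),
    regression = .fit_regression(x, order, method),
    partial = .fit_partial(x, order))
  fit$formalism <- formalism
  fit$n <- x$n
  fit$landscape <- x
  fit$call <- cl
  names(fit$coefficients) <- index_to_genotype(0:(2^x$n - 1L), x$n)
  if (!is.null(fit$sd)) names(fit$sd) <- names(fit$coefficients)
  fit$order <- genotype_order(0:(2^x$n - 1L))
  class(fit) <- "epistasis"
  fit
}

.require_complete <- function(x, formalism) {
  if (!is_complete(x))
    stop("'", formalism, "' requires a complete landscape (all 2^n genotypes);",
         " use formalism = 'partial' or 'regression' for incomplete data")
}

.fit_cycle <- function(x) {
  .require_complete(x, "cycle")
  lam <- subset_mobius(x$phenotype)
  sd <- if (!is.null(x$sd)) sqrt(subset_zeta(x$sd^2))
  list(coefficients = lam, sd = sd, residuals = NULL, rank_ok = TRUE,
       order_limit = NULL)
}

.fit_background <- function(x) {
  .require_complete(x, "background")
  n <- x$n
  q <- genotype_order(0:(2^n - 1L))
  v <- (-1)^q / 2^(n - q)
  eps <- v * fast_wht(x$phenotype)
  sd <- if (!is.null(x$sd)) abs(v) * sqrt(sum(x$sd^2))
  list(coefficients = eps, sd = sd, residuals = NULL, rank_ok = TRUE,
       order_limit = NULL)
}

.fit_regression <- function(x, order, method) {
  n <- x$n
  r <- if (is.null(order)) n else as.integer(order)
  if (r < 0L || r > n) stop("regression order must be in [0, n]")
  q <- genotype_order(0:(2^n - 1L))
  keep <- q <= r
  m <- sum(keep)
  if (is_complete(x) && method == "operator") {
    ## beta = V t(X) S H y, matrix-free
    u <- fast_wht(x$phenotype)
    u[!keep] <- 0
    beta <- ((-1)^q / 2^(n - q)) * superset_sum(u)
    res <- x$phenotype - subset_zeta(beta)
    sd <- if (!is.null(x$sd)) .regression_sd(x, r, keep)
    return(list(coefficients = beta, sd = sd, residuals = res,
                rank_ok = TRUE, order_limit = r))
  }
  s <- sum(x$observed)
  if (s < m)
    stop("only ", s, " observed genotypes for ", m,
         " regression coefficients (order ", r, ")")
  Xt <- interaction_design(n)[x$observed, keep, drop = FALSE]
  storage.mode(Xt) <- "double"
  sv <- svd(Xt, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-8 * sv[1L])
    stop("observed design is rank deficient: some interaction terms are not ",
         "identifiable (e.g. mutations that always co-occur in the data)")
  qrX <- qr(Xt)
  bk <- qr.coef(qrX, x$phenotype[x$observed])
  beta <- numeric(2^n)
  beta[keep] <- bk
  res <- x$phenotype[x$observed] - Xt %*% bk
  sd <- if (!is.null(x$sd)) .regression_sd(x, r, keep)
  list(coefficients = beta, sd = sd, residuals = as.numeric(res),
       rank_ok = TRUE, order_limit = r)
}

## sd of regression coefficients through the explicit solution operator
## P = Q (Xt' Xt)^-1 Xt' M  (rows of the full-length linear map)
.regression_sd <- function(x, r, keep) {
  n <- x$n
  Xt <- interaction_design(n)[x$observed, keep, drop = FALSE]
  storage.mode(Xt) <- "double"
  B <- solve(crossprod(Xt), t(Xt))          # m x s
  dy <- x$sd[x$observed]
  sk <- sqrt((B^2) %*% dy^2)
  out <- numeric(2^n)
  out[keep] <- sk
  out
}

.fit_partial <- function(x, order) {
  n <- x$n
  pmax_ <- complete_order(x)
  p <- if (is.null(order)) pmax_ else as.integer(order)
  if (p < 0L || p > n) stop("averaging order p must be in [0, n]")
  if (pmax_ < p)
    stop("data are complete only up to order ", pmax_,
         "; cannot average partially to order ", p)
  q <- genotype_order(0:(2^n - 1L))
  FM <- partial_hadamard(n, p)
  ## columns of F for genotypes above order p are identically zero, so
  ## unobserved high-order phenotypes are never read
  y0 <- ifelse(x$observed, x$phenotype, 0)
  w <- ifelse(q <= p,
              (-1)^q / vapply(q, function(qq) sum(choose(n - qq, 0:(p - qq))), 1),
              NA_real_)
  eps <- w * as.numeric(FM %*% y0)
  sd <- NULL
  if (!is.null(x$sd)) {
    d0 <- ifelse(x$observed, x$sd, 0)
    sd <- abs(w) * sqrt(as.numeric((FM^2) %*% d0^2))
  }
  list(coefficients = eps, sd = sd, residuals = NULL, rank_ok = TRUE,
       order_limit = p)
}

#' Propagate measurement errors through a linear epistasis operator
#'
#' For independent per-genotype standard deviations `sd`, the standard
#' deviation of coefficient `i` of a spectrum `W y` is
#' `sqrt(sum_j W_ij^2 sd_j^2)` (the element-wise square of the operator
#' applied to the element-wise square of the errors).
#'
#' @param operator a numeric matrix (e.g. from [epistasis_operator()]).
#' @param sd nonnegative numeric vector of per-genotype standard deviations,
#'   one per operator column.
#' @return numeric vector of propagated standard deviations, one per row.
#' @examples
#' propagate_sd(epistasis_operator("cycle", 3), rep(0.1, 8))
#' @export
propagate_sd <- function(operator, sd) {
  if (ncol(operator) != length(sd))
    stop("sd must have one entry per operator column")
  if (any(sd < 0)) stop("sd must be nonnegative")
  sqrt(as.numeric((operator^2) %*% sd^2))
}
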