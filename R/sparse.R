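## Sparse recovery of background-averaged spectra from subsampled landscapes.
##
## The forward model is y = H^-1 V^-1 epsilon; with s observed genotypes the
## constraints are M y = A epsilon with A = M H^-1 V^-1.  When epsilon is
## sparse it can be recovered from s << 2^n phenotypes by l1-norm
## minimisation, the compressive-sensing principle.

## A = M H^-1 V^-1 restricted to observed rows (s x 2^n, dense)
.recovery_matrix <- function(n, observed) {
  q <- genotype_order(0:(2^n - 1L))
  Hinv <- hadamard_matrix(n)[observed, , drop = FALSE] / 2^n
  sweep(Hinv, 2L, (-1)^q * 2^(n - q), `*`)
}

## Basis pursuit (min ||x||_1 s.t. A x = b) by ADMM with a least-squares
## polish on the detected support.  The projection onto {x : A x = b} is
## computed through a cached Cholesky factor of A A'.
.basis_pursuit <- function(A, b, rho = 1, max_iter = 20000L, tol = 1e-10) {
  N <- ncol(A)
  ch <- chol(tcrossprod(A))
  solveAAt <- function(v) backsolve(ch, forwardsolve(t(ch), v))
  x_feas <- as.numeric(crossprod(A, solveAAt(b)))
  project <- function(v)
    v - as.numeric(crossprod(A, solveAAt(A %*% v))) + x_feas
  z <- u <- numeric(N)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    x <- project(z - u)
    znew <- sign(x + u) * pmax(0, abs(x + u) - 1 / rho)
    prim <- max(abs(x - znew))
    dual <- rho * max(abs(znew - z))
    z <- znew
    u <- u + x - z
    if (prim < tol && dual < tol) { converged <- TRUE; break }
  }
  ## polish: exact least squares on the support of the (exactly sparse) z
  sol <- z
  supp <- which(abs(z) > 1e-6 * max(1, max(abs(z))))
  if (length(supp) && length(supp) <= nrow(A)) {
    xp <- numeric(N)
    cf <- try(qr.solve(A[, supp, drop = FALSE], b), silent = TRUE)
    if (!inherits(cf, "try-error")) {
      xp[supp] <- cf
      feas_p <- max(abs(A %*% xp - b))
      if (feas_p < 1e-8 * (1 + max(abs(b))) &&
          sum(abs(xp)) <= sum(abs(z)) + 1e-6 * (1 + sum(abs(z))))
        sol <- xp
    }
  }
  list(x = sol, iterations = k, converged = converged,
       residual = max(abs(A %*% sol - b)))
}

#' Sparse recovery of a background-averaged spectrum by l1 minimisation
#'
#' Finds the background-averaged epistatic spectrum of minimum l1 norm that
#' reproduces the observed phenotypes exactly:
#' `min ||epsilon||_1  subject to  M y = M H^-1 V^-1 epsilon`.
#' With complete data the constraint set is a single point and the result
#' equals the closed-form transform; with fewer observations than
#' coefficients, a sufficiently sparse true spectrum is still recovered
#' exactly -- the compressive-sensing regime.  All coefficients, including
#' the order-0 term, enter the norm.
#'
#' The noiseless problem (`slack = 0`) is solved as a basis-pursuit program
#' by ADMM with a least-squares polish on the detected support.  With
#' `slack > 0` the equality is relaxed to
#' `||M y - A epsilon||_2 <= slack` and solved through the lasso Lagrangian,
#' with the penalty found by bisection on the residual norm.
#'
#' @param x a [genotype_landscape], complete or masked.
#' @param slack nonnegative l2 allowance for noisy constraints (default 0,
#'   exact equality).
#' @param tol ADMM convergence tolerance.
#' @param max_iter ADMM iteration cap.
#' @return an object of class `c("epistasis_recovery", "epistasis")` whose
#'   coefficients are the recovered spectrum (formalism `"background"`),
#'   with fields `l1` (attained norm), `constraint_residual`, `converged`
#'   and `iterations`.
#' @examples
#' # complete data: recovery reproduces the closed-form transform
#' fit <- recover_l1(pdz_binding())
#' max(abs(coef(fit) - coef(epistasis(pdz_binding(), "background"))))
#' @seealso [recover_lasso()], [recovery_phase_curve()]
#' @export
recover_l1 <- function(x, slack = 0, tol = 1e-10, max_iter = 20000L) {
  stopifnot(inherits(x, "genotype_landscape"))
  if (slack < 0) stop("slack must be nonnegative")
  n <- x$n
  A <- .recovery_matrix(n, x$observed)
  b <- x$phenotype[x$observed]
  if (slack == 0) {
    if (all(x$observed)) {
      ## unique feasible point: solve the square linear system
      eps <- solve(A, b)
      sol <- list(x = eps, iterations = 0L, converged = TRUE,
                  residual = max(abs(A %*% eps - b)))
    } else {
      sol <- .basis_pursuit(A, b, max_iter = max_iter, tol = tol)
      if (!sol$converged)
        warning("basis-pursuit ADMM did not reach tolerance ", tol,
                " in ", max_iter, " iterations")
    }
  } else {
    sol <- .l1_slack(A, b, slack)
  }
  .as_recovery(sol, x, mode = if (slack == 0) "exact_constraint" else "slack")
}

## slack > 0: bisection on the lasso penalty so that the l2 residual just
## meets the allowance (basis-pursuit-denoising via its Lagrangian)
.l1_slack <- function(A, b, slack) {
  resid2 <- function(xx) sqrt(sum((A %*% xx - b)^2))
  lo <- 0; hi <- max(abs(crossprod(A, b)))  # at hi the solution is 0
  x_lo <- .lasso_point(A, b, 1e-12)
  if (resid2(x_lo) >= slack)
    return(list(x = x_lo, iterations = 1L, converged = TRUE,
                residual = max(abs(A %*% x_lo - b))))
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    xm <- .lasso_point(A, b, max(mid, 1e-12))
    if (resid2(xm) <= slack) lo <- mid else hi <- mid
  }
  xx <- .lasso_point(A, b, max(lo, 1e-12))
  list(x = xx, iterations = 40L, converged = TRUE,
       residual = max(abs(A %*% xx - b)))
}

## single-penalty lasso solution on the recovery design (glmnet backend);
## penalty is on sum(|epsilon|), objective (1/2)||b - A eps||_2^2 + penalty * l1.
## The first design column (order-0 term) is the all-ones column, so an
## unpenalized intercept is exactly glmnet's native intercept.
.lasso_point <- function(A, b, penalty, penalize_intercept = TRUE) {
  s <- nrow(A)
  lam <- penalty / s   # glmnet objective: (1/(2s)) RSS + lambda ||.||_1
  if (penalize_intercept) {
    fit <- glmnet::glmnet(A, b, family = "gaussian", alpha = 1,
                          lambda = lam, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14, maxit = 1e7)
    as.numeric(fit$beta)
  } else {
    fit <- glmnet::glmnet(A[, -1L, drop = FALSE], b, family = "gaussian",
                          alpha = 1, lambda = lam, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-14, maxit = 1e7)
    c(as.numeric(fit$a0), as.numeric(fit$beta))
  }
}

.as_recovery <- function(sol, x, mode) {
  n <- x$n
  fit <- list(coefficients = sol$x, sd = NULL, residuals = NULL,
              rank_ok = TRUE, order_limit = NULL,
              formalism = "background", n = n, landscape = x,
              call = sys.call(-1L),
              l1 = sum(abs(sol$x)), constraint_residual = sol$residual,
              converged = sol$converged, iterations = sol$iterations,
              mode = mode)
  names(fit$coefficients) <- index_to_genotype(0:(2^n - 1L), n)
  fit$order <- genotype_order(0:(2^n - 1L))
  class(fit) <- c("epistasis_recovery", "epistasis")
  fit
}

#' @export
print.epistasis_recovery <- function(x, digits = 3, ...) {
  cat(sprintf(
    "l1 spectrum recovery (%s): %d sites, %d observations, l1 = %.4g, max constraint residual = %.3g\n",
    x$mode, x$n, sum(x$landscape$observed), x$l1, x$constraint_residual))
  nz <- which(abs(x$coefficients) > 1e-8)
  cat(length(nz), "nonzero coefficients\n")
  df <- as.data.frame(x)[nz, , drop = FALSE]
  print(df, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Lasso estimation of a background-averaged spectrum
#'
#' Minimises `(1/2) ||M y - A epsilon||_2^2 + penalty * ||epsilon||_1` over
#' the recovery design `A = M H^-1 V^-1`: the regularised companion of
#' [recover_l1()] for noisy or heavily subsampled data.  As
#' `penalty -> 0` with complete data the solution converges to the exact
#' background-averaged spectrum (at `penalty = 0` the unpenalised
#' least-squares/interpolating solution is returned directly).
#'
#' @param x a [genotype_landscape].
#' @param penalty nonnegative l1 penalty weight.
#' @param penalize_intercept include the order-0 term in the penalty
#'   (default `TRUE`, matching [recover_l1()]).
#' @return an object of class `c("epistasis_recovery", "epistasis")`.
#' @export
recover_lasso <- function(x, penalty, penalize_intercept = TRUE) {
  stopifnot(inherits(x, "genotype_landscape"))
  if (penalty < 0) stop("penalty must be nonnegative")
  n <- x$n
  A <- .recovery_matrix(n, x$observed)
  b <- x$phenotype[x$observed]
  if (penalty == 0) {
    eps <- if (all(x$observed)) solve(A, b)
           else as.numeric(crossprod(A, solve(tcrossprod(A), b)))
  } else {
    eps <- .lasso_point(A, b, penalty, penalize_intercept)
  }
  sol <- list(x = eps, iterations = NA_integer_, converged = TRUE,
              residual = max(abs(A %*% eps - b)))
  .as_recovery(sol, x, mode = "lasso")
}

#' Exact-recovery phase curve for sparse spectra
#'
#' Monte-Carlo harness mapping when l1 recovery succeeds: over a grid of
#' (sites, sparsity, observation count), simulate landscapes with a random
#' sparse background-averaged truth, subsample genotypes at random, run
#' [recover_l1()], and record the fraction of replicates recovered exactly.
#'
#' @param n number of sites (scalar or vector).
#' @param sparsity numbers of nonzero coefficients beyond none (vector ok).
#' @param observations numbers of observed genotypes (vector ok).
#' @param noise_sd Gaussian measurement noise (passed to the generator;
#'   recovery counts as success when within `success_tol` of truth).
#' @param replicates Monte-Carlo replicates per grid cell.
#' @param seed integer seed; the full grid is deterministic given it.
#' @param success_tol max absolute coefficient error counted as exact.
#' @return data frame with one row per grid cell and column `recovered`
#'   (fraction in `[0, 1]`).
#' @export
recovery_phase_curve <- function(n, sparsity, observations, noise_sd = 0,
                                 replicates = 20L, seed = 1L,
                                 success_tol = 1e-6) {
  grid <- expand.grid(n = n, sparsity = sparsity,
                      observations = observations, noise_sd = noise_sd)
  grid$recovered <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ok <- 0L
    for (rep in seq_len(replicates)) {
      cell_seed <- (seed * 1000L + g * 131L + rep * 7L) %% .Machine$integer.max
      sim <- simulate_landscape(grid$n[g], sparsity = grid$sparsity[g],
                                noise_sd = grid$noise_sd[g],
                                design = "random_s", s = grid$observations[g],
                                seed = cell_seed)
      rec <- suppressWarnings(recover_l1(sim$landscape))
      if (max(abs(coef(rec) - sim$truth)) < success_tol) ok <- ok + 1L
    }
    grid$recovered[g] <- ok / replicates
  }
  grid
}
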