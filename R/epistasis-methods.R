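#' @export
print.epistasis <- function(x, digits = 3, max_rows = 16L, ...) {
  lab <- switch(x$formalism,
    cycle = "Mutant-cycle (reference-based) epistasis",
    background = "Background-averaged epistasis",
    regression = sprintf("Interaction regression (order <= %d)", x$order_limit),
    partial = sprintf("Partial background-averaged epistasis (complete to order %d)",
                      x$order_limit))
  cat(lab, sprintf(" -- %d sites, %d coefficients\n", x$n, 2^x$n), sep = "")
  df <- as.data.frame(x)
  if (nrow(df) > max_rows) {
    print(utils::head(df, max_rows), row.names = FALSE, digits = digits)
    cat("  ... ", nrow(df) - max_rows, " more terms\n", sep = "")
  } else print(df, row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
as.data.frame.epistasis <- function(x, ...) {
  df <- data.frame(term = term_label(0:(2^x$n - 1L), x$n),
                   order = x$order,
                   coefficient = unname(x$coefficients),
                   stringsAsFactors = FALSE)
  if (!is.null(x$sd)) df$sd <- unname(x$sd)
  df
}

#' @export
coef.epistasis <- function(object, ...) object$coefficients

#' Per-order summary of an epistatic spectrum
#'
#' Groups coefficients by interaction order and reports the mean absolute
#' coefficient per order, the hallmark summary of how epistasis scales with
#' order.  When propagated per-term standard deviations are available the
#' error on each mean is reported as the root mean square of the per-term
#' standard deviations within the order.
#'
#' @param object an [epistasis] fit.
#' @param ... unused.
#' @return a `summary.epistasis` object wrapping a data frame with columns
#'   `order`, `terms`, `mean_abs` and (if available) `sd`.
#' @export
summary.epistasis <- function(object, ...) {
  ok <- !is.na(object$coefficients)
  ords <- sort(unique(object$order[ok]))
  tab <- do.call(rbind, lapply(ords, function(k) {
    i <- ok & object$order == k
    data.frame(order = k, terms = sum(i),
               mean_abs = mean(abs(object$coefficients[i])),
               sd = if (is.null(object$sd)) NA_real_
                    else sqrt(mean(object$sd[i]^2)))
  }))
  if (is.null(object$sd)) tab$sd <- NULL
  structure(list(table = tab, formalism = object$formalism, n = object$n,
                 residual_rms = if (!is.null(object$residuals) &&
                                    length(object$residuals))
                   sqrt(mean(object$residuals^2)) else NULL),
            class = "summary.epistasis")
}

#' @export
print.summary.epistasis <- function(x, digits = 3, ...) {
  cat(sprintf("Mean absolute epistatic terms by order (%s formalism, n = %d)\n",
              x$formalism, x$n))
  print(x$table, row.names = FALSE, digits = digits)
  if (!is.null(x$residual_rms))
    cat(sprintf("Residual RMS: %.*g\n", digits, x$residual_rms))
  invisible(x)
}

#' Reconstruct phenotypes from an epistatic spectrum
#'
#' Inverts the fitted decomposition back to the phenotype scale.  The
#' mutant-cycle and full background-averaged transforms are exactly
#' invertible (`y = X lambda` and `y = H^-1 V^-1 epsilon`), so prediction
#' reproduces the input phenotypes to numerical tolerance.  Regression fits
#' predict `X beta`, the least-squares approximation at every genotype
#' (including unobserved ones).  Partial-averaging spectra are lossy: the
#' coefficients above the complete order are unknown, and prediction refuses
#' them unless `zero_fill = TRUE` explicitly sets the missing coefficients
#' to zero.
#'
#' @param object an [epistasis] fit.
#' @param zero_fill treat `NA` (un-estimated) coefficients as zero.
#' @param ... unused.
#' @return named numeric vector of phenotypes over all `2^n` genotypes.
#' @export
predict.epistasis <- function(object, zero_fill = FALSE, ...) {
  beta <- unname(object$coefficients)
  if (anyNA(beta)) {
    if (!zero_fill)
      stop("spectrum is truncated (NA coefficients above order ",
           object$order_limit, "); reconstruction is lossy -- ",
           "use zero_fill = TRUE to force")
    beta[is.na(beta)] <- 0
  }
  y <- switch(object$formalism,
    cycle = subset_zeta(beta),
    regression = subset_zeta(beta),
    ## partial coefficients are zero-filled into the full averaged basis
    partial = ,
    background = {
      n <- object$n
      q <- genotype_order(0:(2^n - 1L))
      fast_wht(beta * (-1)^q * 2^(n - q)) / 2^n
    })
  names(y) <- index_to_genotype(0:(2^object$n - 1L), object$n)
  y
}

#' @export
fitted.epistasis <- function(object, ...) {
  predict(object, zero_fill = object$formalism == "partial")
}

#' @export
residuals.epistasis <- function(object, ...) {
  if (!is.null(object$residuals)) return(object$residuals)
  ls <- object$landscape
  (ls$phenotype - unname(fitted(object)))[ls$observed]
}

#' Spectrum plot of epistatic coefficients by order
#'
#' @param x an [epistasis] fit.
#' @param absolute plot absolute values (default) or signed coefficients.
#' @param ... passed to [graphics::plot()].
#' @export
plot.epistasis <- function(x, absolute = TRUE, ...) {
  ok <- !is.na(x$coefficients)
  co <- unname(x$coefficients[ok])
  if (absolute) co <- abs(co)
  ord <- x$order[ok]
  graphics::plot(jitter(ord, amount = 0.08), co,
                 xlab = "interaction order",
                 ylab = if (absolute) "|coefficient|" else "coefficient",
                 main = paste0(x$formalism, " epistatic spectrum"), ...)
  mu <- tapply(co, ord, mean)
  graphics::lines(as.numeric(names(mu)), mu, type = "b", pch = 4, col = 2)
  invisible(x)
}

#' Simulate replicate landscapes from a fitted spectrum
#'
#' Draws phenotype vectors `y_hat + N(0, sd)` around the reconstruction of
#' the fitted spectrum, using the landscape's per-genotype standard
#' deviations (or a common `sd`).
#'
#' @param object an [epistasis] fit.
#' @param nsim number of replicate landscapes.
#' @param seed optional integer seed.
#' @param sd per-genotype or scalar noise standard deviation; defaults to
#'   the landscape's error column, else 0.
#' @param ... unused.
#' @return data frame with one column per simulated replicate and one row
#'   per genotype.
#' @export
simulate.epistasis <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  yhat <- unname(predict(object, zero_fill = TRUE))
  N <- length(yhat)
  if (is.null(sd)) sd <- if (!is.null(object$landscape$sd))
    ifelse(is.na(object$landscape$sd), 0, object$landscape$sd) else 0
  sims <- vapply(seq_len(nsim),
                 function(k) yhat + stats::rnorm(N, 0, sd), numeric(N))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- index_to_genotype(0:(N - 1L), object$n)
  out
}
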