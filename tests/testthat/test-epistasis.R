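rand_masked <- function() {
  ls <- rand_landscape(3, 7)
  ls$phenotype[8] <- NA
  ls$observed[8] <- FALSE
  ls
}

test_that("mutant-cycle terms are reference-based interaction free energies", {
  fit <- epistasis(pdz_binding(), "cycle")
  lam <- coef(fit)
  y <- pdz_binding()$phenotype
  expect_equal(unname(lam[1]), y[1])                      # reference value
  expect_equal(unname(lam["001"]), y[2] - y[1])           # single-mutant effect
  # second-order term = double-mutant-cycle coupling
  expect_equal(unname(lam["011"]), (y[4] - y[3]) - (y[2] - y[1]))
  expect_error(epistasis(rand_masked(), "cycle"), "complete")
})

test_that("background-averaged terms average couplings over all backgrounds", {
  ls <- rand_landscape(3, 21)
  y <- ls$phenotype
  eps <- coef(epistasis(ls, "background"))
  expect_equal(unname(eps[1]), mean(y))
  # the explicit two-background average of the site-2:site-1 coupling
  expect_equal(unname(eps["011"]),
               (((y[8] - y[7]) - (y[6] - y[5])) +
                ((y[4] - y[3]) - (y[2] - y[1]))) / 2)
  # constant landscapes carry no epistasis at any order
  flat <- epistasis(genotype_landscape(rep(4.2, 16)), "background")
  expect_equal(unname(coef(flat)), c(4.2, rep(0, 15)))
})

test_that("additive landscapes have zero terms above order one in all formalisms", {
  for (n in 3:5) {
    set.seed(n)
    a <- rnorm(n)
    idx <- 0:(2^n - 1)
    y <- vapply(idx, function(i)
      sum(a[which(bitwAnd(i, 2^(0:(n - 1))) > 0)]), numeric(1))
    ls <- genotype_landscape(y, n = n)
    q <- genotype_order(idx)
    for (f in c("cycle", "background", "regression"))
      expect_equal(max(abs(coef(epistasis(ls, f))[q >= 2])), 0,
                   tolerance = 1e-12)
  }
})

test_that("highest-order term is identical across cycle and background averaging", {
  for (n in 2:8) {
    ls <- rand_landscape(n, n + 50)
    lam <- coef(epistasis(ls, "cycle"))
    eps <- coef(epistasis(ls, "background"))
    expect_equal(lam[2^n], eps[2^n], tolerance = 1e-10)
  }
})

test_that("full-order regression equals the mutant cycle with zero residuals", {
  for (n in 2:5) {
    ls <- rand_landscape(n, n)
    fit <- epistasis(ls, "regression")   # r defaults to n
    expect_equal(coef(fit), coef(epistasis(ls, "cycle")), tolerance = 1e-10)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
  # intercept-only regression is the grand mean
  ls <- rand_landscape(4, 9)
  fit0 <- epistasis(ls, "regression", order = 0)
  expect_equal(unname(coef(fit0)[1]), mean(ls$phenotype))
  expect_equal(max(abs(coef(fit0)[-1])), 0)
})

test_that("operator route and normal equations give the same regression fit", {
  for (n in 2:6) {
    ls <- rand_landscape(n, 30 + n)
    for (r in 0:n) {
      b_qr <- epistasis(ls, "regression", order = r, method = "qr")
      b_op <- epistasis(ls, "regression", order = r, method = "operator")
      expect_equal(coef(b_qr), coef(b_op), tolerance = 1e-9)
      expect_equal(residuals(b_qr), residuals(b_op), tolerance = 1e-9)
      # structural zeros above the truncation order
      q <- genotype_order(0:(2^n - 1))
      expect_equal(max(abs(coef(b_qr)[q > r]), 0), 0)
    }
  }
})

test_that("regression at the top retained order equals background averaging", {
  for (n in 2:5) for (r in 1:n) {
    ls <- rand_landscape(n, 60 + n + r)
    q <- genotype_order(0:(2^n - 1))
    beta <- coef(epistasis(ls, "regression", order = r))
    eps <- coef(epistasis(ls, "background"))
    expect_equal(beta[q == r], eps[q == r], tolerance = 1e-10)
  }
})

test_that("site relabelling permutes coefficients consistently", {
  for (n in 3:5) {
    ls <- rand_landscape(n, 80 + n)
    set.seed(n)
    perm <- sample(n)  # new position of each site
    idx <- 0:(2^n - 1)
    remap <- vapply(idx, function(i) {
      bits <- as.integer(bitwAnd(i, 2^(0:(n - 1))) > 0)
      sum(bits[perm] * 2^(0:(n - 1)))
    }, numeric(1))
    ls_p <- genotype_landscape(ls$phenotype[remap + 1], n = n)
    for (f in c("cycle", "background")) {
      co <- coef(epistasis(ls, f))
      co_p <- coef(epistasis(ls_p, f))
      expect_equal(unname(co_p), unname(co[remap + 1]), tolerance = 1e-10)
    }
  }
})

test_that("invertible spectra reconstruct the landscape exactly", {
  for (n in c(3, 6, 10)) {
    ls <- rand_landscape(n, 200 + n)
    for (f in c("cycle", "background")) {
      fit <- epistasis(ls, f)
      expect_equal(unname(predict(fit)), ls$phenotype, tolerance = 1e-9)
      expect_lt(max(abs(residuals(fit))), 1e-9)
    }
  }
  # zero spectrum reconstructs a zero landscape
  z <- epistasis(genotype_landscape(rep(0, 8)), "cycle")
  expect_equal(max(abs(predict(z))), 0)
})

test_that("measurement errors propagate through the operator rows", {
  # uniform noise: mutant-cycle sd grows as sigma * 2^(q/2)
  sig <- 0.3
  for (n in c(3, 5)) {
    ls <- genotype_landscape(rnorm(2^n), n = n, sd = rep(sig, 2^n))
    q <- genotype_order(0:(2^n - 1))
    fit <- epistasis(ls, "cycle")
    expect_equal(unname(fit$sd), sig * 2^(q / 2), tolerance = 1e-12)
    bg <- epistasis(ls, "background")
    expect_equal(unname(bg$sd), sig * 2^(q - n / 2), tolerance = 1e-12)
  }
  # zero errors give zero coefficient errors
  ls0 <- genotype_landscape(rnorm(8), sd = rep(0, 8))
  expect_equal(max(epistasis(ls0, "cycle")$sd), 0)
  # propagate_sd agrees with the per-formalism shortcut on general errors
  ls <- rand_landscape(4, 3, with_sd = TRUE)
  for (f in c("cycle", "background")) {
    fit <- epistasis(ls, f)
    op <- epistasis_operator(f, 4)
    expect_equal(unname(fit$sd), propagate_sd(op, ls$sd), tolerance = 1e-12)
  }
})

test_that("order summary reports mean absolute coefficients with RMS errors", {
  # a single nonzero term c at order k yields the row (k, |c|)
  co <- numeric(8); co[4] <- -1.5  # genotype 011, order 2
  ls <- genotype_landscape(subset_zeta(co), n = 3)
  tab <- summary(epistasis(ls, "cycle"))$table
  expect_equal(tab$mean_abs[tab$order == 2], 1.5 / 3)  # averaged over C(3,2) terms
  expect_equal(tab$terms, choose(3, 0:3))

  fit <- epistasis(shaker_gating(), "cycle")
  tab <- summary(fit)$table
  q <- genotype_order(0:15)
  expect_equal(tab$mean_abs[4], mean(abs(coef(fit)[q == 3])))
  expect_equal(tab$sd[4], sqrt(mean(fit$sd[q == 3]^2)))
})

test_that("signed +/-1 encoding reproduces background averaging up to 2^q", {
  # n = 1: the signed slope is half the phenotype difference
  ls1 <- genotype_landscape(c(1.2, 3.0), n = 1)
  sc1 <- signed_encoding(ls1)
  expect_equal(sc1$beta_signed[2], (3.0 - 1.2) / 2)
  expect_equal(sc1$epsilon[2], 2 * sc1$beta_signed[2])

  for (n in 2:4) {
    sc <- signed_encoding(rand_landscape(n, 5 * n))
    expect_true(sc$consistent)
    expect_equal(unname(sc$ratio_by_order), 2^(0:n))
  }
  # constant landscape: all non-intercept signed coefficients vanish
  scc <- signed_encoding(genotype_landscape(rep(2, 8)))
  expect_equal(max(abs(scc$beta_signed[-1])), 0, tolerance = 1e-12)
})

test_that("fit methods print, plot and simulate coherently", {
  fit <- epistasis(pdz_binding(), "background")
  expect_output(print(fit), "Background-averaged")
  expect_output(print(summary(fit)), "mean_abs")
  df <- as.data.frame(fit)
  expect_equal(df$term[6], "1*1")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8L, 3L))
  # noise-free simulation from an sd-free fit reproduces the reconstruction
  fit2 <- epistasis(genotype_landscape(rnorm(8)), "cycle")
  expect_equal(sims_ok <- simulate(fit2, nsim = 1)$sim_1,
               unname(predict(fit2)))
})
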