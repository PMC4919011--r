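---
title: "Decomposing genotype-phenotype landscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genotype-phenotype landscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwalsh)
```

## The model

A landscape assigns a quantitative phenotype $y_g$ to each of the $2^n$
combinations of binary states at $n$ mutable sites. The null hypothesis
throughout is additivity: independence of two mutations means their joint
effect is the sum of their single effects on the chosen scale. Phenotypes
must therefore already live on an additive scale — for binding data that is
the free energy $\Delta G = RT\ln K_d$ (helper `kd_to_free_energy()`,
$R = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$, default $T = 298.15$ K; the
packaged case-study free energies are stored as published rather than
recomputed from dissociation constants, whose measurement temperature is
not part of the packaged data).

Genotypes are indexed by bitmask $i \in \{0, \dots, 2^n-1\}$, site $n$
printed leftmost, index 0 the all-wild-type reference; the interaction
order $q_i$ of a coefficient is the population count of $i$. Three
classical quantifications of epistasis are all weighted Walsh–Hadamard
transforms of $\bar y$:

* **Mutant cycle** $\bar\lambda = G\bar y$: interactions relative to one
  reference genotype; $G$ is the signed inclusion–exclusion operator over
  the subset lattice, the inverse of the 0/1 interaction design $X$.
  Computed matrix-free as the Möbius butterfly (`subset_mobius()`).
* **Background-averaged** $\bar\varepsilon = VH\bar y$: each order-$q$
  interaction averaged over all $2^{n-q}$ genotypic backgrounds of the
  remaining sites, $V = \mathrm{diag}\!\big((-1)^{q_i}/2^{n-q_i}\big)$.
  Computed as `fast_wht()` plus the diagonal weights.
* **Truncated regression** $\hat\beta = (\hat X^\top \hat X)^{-1}
  \hat X^\top \bar y$ with $\hat X = XQ$, keeping orders $\le r$.
  Coefficients above $r$ are stored as structural zeros so every spectrum
  has full length $2^n$.

The identities $G = X^{-1}$ (exact in integer arithmetic),
$G = VX^\top H$, and "regression $=$ $VX^\top S H$" tie the formalisms
together; the test suite verifies each of them bit-exactly or to $10^{-10}$
against independent closed forms (popcount rules, `solve()`, brute-force
subset tests) for $n \le 8$.

## Incomplete data

Two analytically clean incomplete-data regimes are supported:

* **Partial background averaging** (`formalism = "partial"`), for data
  complete up to mutation order $p$:
  $\bar\varepsilon_p = W_p (Z_p \circ H)\bar y$, where $Z_p$ zeroes the
  Hadamard entries touching genotypes above order $p$ (equivalently
  $Z_p[i,j] = 1$ iff $\mathrm{popcount}(i\,|\,j) \le p$ — a characterisation
  the tests confirm against the block recursion rather than assume) and
  $W_p = \mathrm{diag}\!\big((-1)^{q}/T_{p,q}\big)$ with
  $T_{p,q} = \sum_{j=0}^{p-q}\binom{n-q}{j}$ counting the remaining
  backgrounds. Columns of $Z_p \circ H$ for genotypes above order $p$ are
  identically zero, so unobserved phenotypes are never read (the suite
  checks this by poisoning them). Coefficients above order $p$ are not
  estimable and are returned as `NA`; reconstruction from a partial
  spectrum consequently requires an explicit `zero_fill = TRUE`.
* **Incomplete regression**: least squares restricted to the observed rows
  $M\bar y$. The design $\tilde X = MXQ$ is solved by rank-revealing QR,
  with identifiability tested via the smallest singular value at a relative
  threshold of $10^{-8}$: literally inverting $\tilde X^\top\tilde X$ would
  silently produce one of infinitely many solutions when, say, two
  mutations always co-occur, and the package instead fails loudly there.
  At least $m = \sum_{k\le r}\binom{n}{k}$ observations are required;
  with exactly $m$ independent rows the fit interpolates.

## Error propagation

With independent per-genotype standard deviations $\delta y_j$, any linear
spectrum $\bar\omega = \Omega \bar y$ has
$\delta\omega_i = \big(\sum_j \Omega_{ij}^2\,\delta y_j^2\big)^{1/2}$.
For uniform noise $\sigma$ this gives $\sigma 2^{q/2}$ for mutant-cycle
terms (growth by $\sqrt 2$ per order) and $\sigma 2^{q-n/2}$ for
background-averaged terms (growth by 2 per order), coinciding at $q = n$.
`noise_scaling_experiment()` reproduces these rates by Monte Carlo on a
flat landscape; its defaults ($n = 14$, $\sigma = 1$, 100 replicates — the
replicate count is exposed as a parameter since it is a pure Monte-Carlo
resolution choice) display the two growth laws over enough orders to
separate cleanly, while the test suite exercises $n = 10$ with 200
replicates, where the same closed forms are resolved well inside the
3-standard-error bands used for checking.

Per-order summaries (`summary()`) report the mean absolute coefficient per
order and, as the error on that mean, the root mean square of the per-term
propagated standard deviations — the convention that reproduces the
published per-order errors of the packaged Shaker table to the printed
precision.

## Sparse recovery

Background-averaged spectra of real systems are believed to be sparse: a
small core of strong couplings in a milieu of weak ones. That motivates
recovering $\bar\varepsilon$ from $s \ll 2^n$ phenotypes by compressive
sensing:

$$\min_{\bar\varepsilon} \|\bar\varepsilon\|_1 \quad\text{s.t.}\quad
M\bar y = M H^{-1} V^{-1} \bar\varepsilon .$$

Design choices, since the masked generalisation and the treatment of noise
are open in the underlying formalism:

* The constraint is imposed on the **observed entries only** ($M$ rows);
  with a full mask the feasible set is the single point $VH\bar y$ and the
  program reduces to the complete-data transform (solved directly as a
  linear system in that case — still an independent computational route
  from the forward transform).
* The equality-constrained problem is solved by **ADMM basis pursuit**
  (splitting the $\ell_1$ objective from the affine constraint, projection
  via a cached Cholesky factor of $AA^\top$), followed by a least-squares
  polish on the detected support, accepted only when it preserves
  feasibility and does not increase the $\ell_1$ norm. The polish turns
  $\sim 10^{-9}$ ADMM accuracy into machine precision on identifiable
  supports. Default tolerance $10^{-10}$, iteration cap 20000.
* The order-0 term is penalised like every other coefficient (the norm is
  over the whole spectrum); `recover_lasso()` optionally exempts it.
* **Noise** enters as an explicit slack: $\|A\bar\varepsilon - M\bar y\|_2
  \le$ `slack`, solved through the lasso Lagrangian with the penalty found
  by bisection on the residual norm. `recover_lasso()` exposes the
  Lagrangian form directly (glmnet backend, penalty on
  $\tfrac12\|A\varepsilon - b\|_2^2 + \text{penalty}\,\|\varepsilon\|_1$).
* Brute-force vertex enumeration over column subsets serves as the
  $\ell_1$ oracle at small $n$; because the optimum need not be unique
  there, tests certify feasibility plus attainment of the minimal norm
  rather than coefficient-wise equality.

`recovery_phase_curve()` maps the success region empirically (fraction of
exact recoveries over a seed-deterministic grid).

## The synthetic generator

`simulate_landscape()` draws landscapes from the exact forward model
$\bar y = H^{-1}V^{-1}\bar\varepsilon_{\text{truth}}$ plus independent
Gaussian measurement noise, with observation designs `complete`,
`up_to_order_p`, `random_s`, and `single_reference_neighborhood`. Random
sparse truths place `sparsity` nonzero coefficients at uniform bitmasks
with magnitudes uniform on $[0.5, 3]$ and random sign — comparable to the
few-kcal/mol couplings of the packaged case studies, and bounded away from
zero so that "exact support recovery" is well defined. It emulates sparse
spectra and homoscedastic Gaussian noise only: it does not model nonlinear
phenotype scales (global epistasis), genotype-dependent measurement error,
missingness correlated with fitness, or thermodynamic ensembles. Passing
parameter-recovery tests on these landscapes therefore validates the
algebra and the estimators, not the biological realism of any particular
dataset.

## Numerical choices and limitations

* Operator recursions are integer-valued and kept in integer arithmetic
  until weights are applied, so identity tests are bit-exact.
* Dense operator matrices are capped at $n \le 14$; beyond that only the
  $n2^n$ matrix-free butterflies are offered. Fits use the matrix-free
  paths for all complete-data formalisms regardless of $n$.
* Duplicate genotypes in input files are an error, never silently
  averaged; non-binary characters and ragged genotype strings likewise.
* Published case-study inputs are stored as printed (two decimals), so
  recomputed interaction terms carry a $\pm 0.02$ kcal/mol reproduction
  tolerance ($\pm 0.03$ for the $n = 4$ case whose operator rows sum more
  rounded inputs); that tolerance is about input rounding, not numerical
  error, which is at machine precision.
* Only biallelic sites are supported; multi-allelic landscapes need a
  $q$-ary Fourier basis outside the present scope. Coefficients are not
  given sampling-based confidence intervals beyond propagated measurement
  error.

```{r}
# the three formalisms on the PDZ case study, side by side
ls <- pdz_binding()
data.frame(term = term_label(0:7, 3),
           cycle = round(coef(epistasis(ls, "cycle")), 2),
           background = round(coef(epistasis(ls, "background")), 2),
           regression_r2 = round(coef(epistasis(ls, "regression", order = 2)), 2))
```
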