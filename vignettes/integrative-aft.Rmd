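---
title: "Integrative penalized AFT models across cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative penalized AFT models across cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`aftfuse` analyzes overall survival in K cancer cohorts simultaneously.
For subject i in cohort k, let `T_ik` be the log survival time, `C_ik` the
log censoring time, `y_ik = min(T_ik, C_ik)` the observed log time and
`delta_ik` the event indicator. The accelerated failure time (AFT) model
takes the log time to be linear in gene expression, either one gene at a
time (the *marginal* model, one tiny model per gene) or with all p genes
at once (the *joint* model).

Censoring is handled by Kaplan–Meier (Stute) weighted least squares: with
each cohort sorted ascending in observed time, the weights

    w_1 = delta_1 / n,
    w_i = delta_i / (n - i + 1) * prod_{l < i} ((n - l)/(n - l + 1))^delta_l

are the jumps of the Kaplan–Meier estimator of the time distribution.
Censored rows get weight zero and the events around them absorb their
mass, so ordinary least squares on the weighted rows is a consistent
estimating procedure for the AFT coefficients. `compute_km_weights()` is
tested to agree with the jumps of an independent Kaplan–Meier
implementation to 1e-12.

The fitted objective, for the joint model, is

    sum_k (1/(2 n_k)) sum_i w_ik (y_ik - alpha_k - X_ik beta_k)^2
      + sum_k sum_j MCP(beta_jk; lambda_sparsity, gamma)
      + (lambda_fusion / 2) sum_j sum_{k' != k} rho(beta_jk, beta_jk')

and analogously per gene for the marginal model. MCP (minimax concave
penalty) performs within-cohort selection with little bias on large
coefficients. The fusion term `rho` couples the cohorts:

* **magnitude fusion**: `(beta_jk - s * beta_jk')^2` with `s = 1` exactly
  when the two coefficients share a sign (`sign(0) = 0`); same-signed
  effects are pulled toward equal size, opposite-signed ones are shrunk
  individually — *quantitative* similarity;
* **sign fusion**: `(sign(beta_jk) - sign(beta_jk'))^2`; only the
  direction of the effect is pushed toward agreement — *qualitative*
  similarity.

Sums run over ordered cohort pairs, so with the `lambda_fusion/2`
prefactor every unordered pair carries weight `lambda_fusion`. A
coefficient shrunk exactly to zero contributes 1 per disagreeing ordered
pair to the sign penalty (the `sign(0) = 0` convention).

With `lambda_fusion = 0` both models collapse, cohort by cohort, to
ordinary MCP-penalized weighted AFT fits — the unintegrated benchmark
(approaches A3/B3 in the simulation study).

## Optimization

Both solvers run cyclic coordinate descent on a standardized scale:
within each cohort, `y` and every column of `X` are centered by their
KM-weighted means, and each column is scaled so `sum(w x^2)/n = 1`. This
absorbs the intercepts (recovered afterwards from the standardization
record) and makes the curvature of every scalar subproblem exactly
`1 + (fusion terms) > 1/gamma`, so each coordinate update

    argmin_theta  0.5 a theta^2 - u theta + MCP(theta; lambda, gamma)

has the closed-form solution `soft(u, lambda)/(a - 1/gamma)` when
`|u| <= a gamma lambda` and `u/a` beyond — implemented in `mcp_prox()` and
verified against dense grid search. Penalties therefore act on
standardized coefficients (the glmnet/ncvreg convention); reported
coefficients are mapped back to the data scale.

The fusion terms are nonsmooth in the sign pattern. Once per sweep the
solver freezes a *fusion state*: the sign-agreement indicators for
magnitude fusion, or the smoothed-sign denominators `d = sqrt(beta^2 +
tau)` for sign fusion (the surrogate `beta/d` stands in for `sign(beta)`;
`tau` defaults to 1e-2 on the standardized scale). Each sweep then
minimizes a fixed quadratic-plus-MCP surrogate coordinate by coordinate,
which gives a testable per-sweep monotonicity property; the state is
refreshed between sweeps. Convergence is declared when the largest
coefficient change falls below `tol * (1 + max |coef|)` (`tol = 1e-4`,
`max_iter = 500` by default). The joint solver iterates on the active set
between full sweeps, maintains residual information through per-cohort
Gram matrices (O(p) per coordinate update), and warm-starts along tuning
paths.

Two numerical choices deserve a note:

* *Marginal multi-start.* The exact objective is nonconvex in the sign
  indicators, and a single all-zero start occasionally converges to a
  fixed point that a 201x201 grid can beat. The marginal solver therefore
  tries three deterministic starts (zero, the unpenalized per-cohort fit,
  and the fusion-free MCP fit) and returns the lowest exact objective.
  The joint solver, where multi-start would be costly, keeps the
  conventional zero/warm start.
* *Degenerate columns.* Columns with zero KM-weighted variance cannot be
  standardized; they are flagged, excluded from fitting, and reported
  with coefficient zero.

## Tuning

The penalty levels are chosen on a grid: sparsity levels log-spaced from
`lambda_max` (the smallest level at which the all-zero fit is stationary,
`max_jk |(1/n_k) sum_i w x y^c|`) down to `0.05 * lambda_max` (25 values
by default), crossed with fusion levels expressed as multipliers
`{0, 0.1, 1, 10}` of the sparsity level. The default grid includes
multiplier 0 so integration is only adopted when it helps.

`select_lambdas_cv()` is the headline selector: V = 5 folds drawn within
each cohort and stratified by event status; the held-out loss is the
KM-weighted squared prediction error with weights recomputed on the
held-out rows; ties go to the sparser, then more fused, pair. One
subtlety: the CV loss of the null model equals the intercept-only loss
only when the sparsity level also exceeds every *training fold's* own
threshold — random folds do not guarantee that at exactly `lambda_max`,
so the test suite verifies the identity at an explicitly inflated level.

`select_lambdas_bic()` is the fast alternative used by the simulation
study: `sum_k n_k log(weighted RSS_k / sum w_k) + log(n_k) df_k` on the
full data, `df` counting nonzero coefficients. With quadratic
(ridge-like) fusion the nonzero count slightly overstates complexity,
but it is the standard MCP choice and is kept deliberately simple.

## The simulation world

`simulate_multicancer()` reproduces a data-based simulation design at any
scale. Defaults state the emulated world explicitly: K = 9 cohorts with
sample sizes 802, 409, 541, 159, 199, 509, 497, 582, 184; 10 causal genes
per cohort; standard normal AFT errors; exponential censoring calibrated
by bisection (on the closed-form expected censored fraction, which is
monotone in the rate) to a 20% target. Scenarios: I — shared causal set,
effects 5; II — effects 2; III — effects Uniform(1, 5) per gene and
cohort; IV — five shared causal genes (effect 2) plus five cohort-specific
ones. Within each cohort's causal list the first five genes act linearly
and the last five *quadratically*, so the generating model is deliberately
richer than the linear AFT being fitted.

Predictors come either from a real expression pool (rows resampled with
replacement per cohort, a shared random subset of p genes per replicate)
or from a synthetic generator: standard normal columns with AR(1)
correlation `rho = 0.3` between adjacent genes, a modest stand-in for the
local dependence of expression data. The synthetic mode is the test
default so nothing needs downloading.

What a green test does and does not establish. The synthetic predictors
are symmetric, so a purely quadratic effect `x^2 beta` has exactly zero
linear marginal signal (`E[x * x^2] = 0`); real expression values are
skewed, which is precisely what makes quadratic genes partially
detectable in real-data-based runs. Consequently the scaled simulation
study reproduces the *FPR* advantage and the cross-cohort agreement (NG)
of the integrative approaches, but their *TPR* advantage — which in the
original setting rides on skewed predictors — does not materialize here:
fusion has no signal to amplify for the quadratic half of the causal set
and trades a little TPR for its FPR gain. The acceptance suite asserts
the TPR/NG dominance as specified and the TPR part is expected to stay
red in this world; we prefer that honest outcome to quietly skewing the
generator after the fact.

Randomness is organized as one master seed fanning out to labeled
substreams (predictors, effects, noise, censoring, folds, replicates), so
every component is independently reproducible.

## Evaluation metrics

* `relative_overlap()` — Jaccard index of two selected-gene sets; both
  empty is defined as 0 with a warning.
* `relative_euclidean_distance()` —
  `sum (a-b)^2 / sqrt(sum a^2 * sum b^2)`; 0 iff equal, 2 for equal-norm
  orthogonal vectors; undefined (error) if either vector is all zero.
* `cluster_cancers()` — average-linkage agglomeration of the cohort
  distance matrix (delegated to `stats::hclust`, with lowest-index
  tie-breaking).
* `c_statistic()` — Harrell-type censoring-aware concordance over usable
  pairs (`y_i < y_j`, `delta_i = 1`), score ties counting 1/2; the raw
  value is returned alongside a `[0.5, 1]`-clipped version for summary
  tables. An IPCW (Uno-type) variant is available via `method = "ipcw"`;
  the pairwise estimator is the default because it is exactly testable
  against brute-force enumeration.
* `identification_metrics()` — TPR/FPR averaged per cohort then across
  cohorts, and NG, the number of genes causal in *every* cohort and
  selected in every cohort (so NG is at most 5 under Scenario IV).

## Known limitations

* The joint solver's Gram-matrix strategy targets p up to a few thousand;
  beyond that, memory for K dense p x p matrices dominates.
* Sign-fusion fixed points are validated against the smoothed surrogate
  objective, not the discontinuous sign penalty itself.
* No left truncation or interval censoring; no normalization or batch
  correction (inputs are assumed preprocessed, level-3-style).
* Marginal p-value/FDR screening is intentionally out of scope; selection
  is purely penalization-based.
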