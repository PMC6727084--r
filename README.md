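# aftfuse

Integrative penalized accelerated failure time (AFT) models for analyzing
survival and gene expression across **multiple cancer cohorts at once**.

Single-cohort prognostic modeling of high-dimensional expression data is
starved for information: cohorts are moderate in size, signals are weak,
and censoring discards part of what little there is. Yet many cancers
share prognostic biology. `aftfuse` borrows strength *during* marker
discovery rather than after it: every cohort keeps its own coefficients
(no sample stacking, heterogeneity is respected), but a fusion penalty
pulls the per-gene effects of different cohorts toward agreement.

## The model

For subject i in cohort k (k = 1..K), with log observed time `y_ik`,
event indicator `delta_ik` and expression `X_ik`, the joint model
minimizes

    sum_k 1/(2 n_k) sum_i w_ik (y_ik - alpha_k - X_ik beta_k)^2
      + sum_{k,j} MCP(beta_jk; lambda_s, gamma)
      + lambda_f / 2 sum_j sum_{k' != k} rho(beta_jk, beta_jk')

where `w_ik` are Kaplan–Meier (Stute) weights — the jumps of the KM
estimator of the time distribution, which make weighted least squares
valid under right censoring — MCP is the minimax concave penalty doing
within-cohort gene selection, and `rho` is either

* **magnitude fusion** `(beta_jk - s beta_jk')^2`, `s = 1` iff the signs
  agree: same-signed effects are pulled toward equal size, or
* **sign fusion** `(sign beta_jk - sign beta_jk')^2`: only effect
  directions are reconciled.

A *marginal* variant fits the same structure one gene at a time. With
`lambda_f = 0` everything reduces to separate per-cohort MCP fits.
Optimization is coordinate descent with exact scalar MCP updates;
see `vignettes/integrative-aft.Rmd` for the numerical details.

## Worked example

Simulate three cohorts (Scenario II: 10 causal genes per cohort, effects
2, five acting quadratically; ~20% exponential censoring), fit the joint
model with magnitude fusion, and score the result:

```r
library(aftfuse)
scen <- simulation_scenario("II", p = 30,
                            n_per_cohort = c(BRCA = 150, LUAD = 150, OV = 150),
                            seed = 42)
sim  <- simulate_multicancer(scen)
w    <- compute_km_weights_all(sim$data)
lmax <- lambda_max(sim$data, w)           # 0.267: smallest all-zero level
spec <- penalty_spec("magnitude", lambda_sparsity = 0.3 * lmax,
                     lambda_fusion = 0.3 * lmax)
fit  <- fit_joint(sim$data, w, spec)
#> <joint_fit: 30 genes x 3 cohorts, 16 nonzero, 12 sweeps, converged>

identification_metrics(fit$selected, sim$truth)
#> TPR = 0.50, FPR = 0.017, NG = 5
```

TPR 0.50 with FPR 0.017 means the five linear causal genes are found in
every cohort (NG = 5) at almost no false positives; the five quadratic
genes are invisible to a linear fit of symmetric predictors — exactly the
misspecification the generator builds in. Cross-cohort agreement of the
selected sets (Jaccard / relative overlap):

```r
evaluate_similarity(fit)$rol
#>       BRCA  LUAD    OV
#> BRCA 1.000 0.833 0.833
#> LUAD 0.833 1.000 1.000
#> OV   0.833 1.000 1.000

sc <- predict_survival_scores(fit, sim$data$datasets[[1]], "BRCA")
c_statistic(sc, sim$data$datasets[[1]]$y, sim$data$datasets[[1]]$delta)$c
#> 0.762   (in-sample concordance)
```

Real cBioPortal-style exports are loaded with `load_cancer_dataset()`,
aligned with `align_genes()` (optionally against a gene panel), and tuned
with `select_lambdas_cv()` / `select_lambdas_bic()`. A command-line
interface wraps the pipeline:

```sh
Rscript -e 'aftfuse::run_command(commandArgs(TRUE))' \
  simulate --scenario I --p 50 --replicates 5 \
  --n-per-cohort 100,100,100 --seed 7 --out study_out
```

Subcommands: `simulate`, `fit-marginal`, `fit-joint`, `tune`, `evaluate`,
`predict`.

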