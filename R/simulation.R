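#' Default cohort sample sizes
#'
#' The nine-cohort sample-size configuration the simulation emulates
#' (BRCA 802, BLCA 409, GBM 541, HNSC 159, LAML 199, LUAD 509, LUSC 497,
#' OV 582, PAAD 184).
#'
#' @return Named integer vector of length 9.
#' @export
default_cohort_sizes <- function() {
  c(BRCA = 802L, BLCA = 409L, GBM = 541L, HNSC = 159L, LAML = 199L,
    LUAD = 509L, LUSC = 497L, OV = 582L, PAAD = 184L)
}

#' Describe a simulation scenario
#'
#' Scenarios differ in how the 10 causal genes per cohort get their
#' effects: I — shared causal set, all effects 5; II — shared set, effects
#' 2; III — shared set, effects drawn Uniform(1, 5) independently per gene
#' and cohort; IV — genes 1-5 shared with effect 2 plus five
#' cohort-specific causal genes with effect 2. Within each cohort's causal
#' list the first five act linearly and the last five quadratically in the
#' generating model, which is therefore deliberately misspecified relative
#' to the linear AFT being fitted.
#'
#' @param scenario one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param p number of predictors (>= 10; >= 15 under IV).
#' @param n_per_cohort integer vector of cohort sizes (defines K).
#' @param censor_target target censoring fraction (default 0.20).
#' @param rho autoregressive column-correlation of the synthetic predictor
#'   generator (default 0.3).
#' @param seed integer seed.
#' @return A `simulation_scenario` object.
#' @export
simulation_scenario <- function(scenario = c("I", "II", "III", "IV"),
                                p = 200,
                                n_per_cohort = default_cohort_sizes(),
                                censor_target = 0.20,
                                rho = 0.3,
                                seed = 1) {
  scenario <- match.arg(scenario)
  if (p < 10) stop("need p >= 10 for the 10 causal genes", call. = FALSE)
  if (scenario == "IV" && p < 15) {
    stop("Scenario IV needs p >= 15 (5 shared + 5 cohort-specific causal genes)",
         call. = FALSE)
  }
  if (censor_target <= 0 || censor_target >= 1) {
    stop("`censor_target` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(scenario = scenario, p = p, K = length(n_per_cohort),
         n_per_cohort = n_per_cohort, causal_count = 10L,
         censor_target = censor_target, rho = rho, seed = seed),
    class = "simulation_scenario"
  )
}

#' Generate predictor matrices for every cohort
#'
#' Synthetic mode (default): mean-zero unit-variance Gaussian columns with
#' AR(1) correlation `rho` between adjacent genes, emulating the local
#' dependence of expression data. Real-pool mode: rows of `source` are
#' resampled with replacement per cohort and a shared set of p genes is
#' drawn uniformly without replacement.
#'
#' @param n_per_cohort integer vector of cohort sizes.
#' @param p number of genes.
#' @param seed integer seed.
#' @param source optional samples x genes numeric pool for real-pool mode.
#' @param rho AR(1) correlation for synthetic mode.
#' @return List of n_k x p matrices, one per cohort.
#' @export
generate_predictors <- function(n_per_cohort, p, seed, source = NULL,
                                rho = 0.3) {
  K <- length(n_per_cohort)
  with_seed(seed, {
    if (is.null(source)) {
      lapply(seq_len(K), function(k) {
        n <- n_per_cohort[k]
        Z <- matrix(stats::rnorm(n * p), n, p)
        if (rho != 0) {
          X <- Z
          for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * Z[, j]
          X
        } else {
          Z
        }
      })
    } else {
      source <- as.matrix(source)
      if (p > ncol(source)) {
        stop("p exceeds the width of the predictor pool", call. = FALSE)
      }
      genes <- sample(ncol(source), p)    # shared across cohorts
      lapply(seq_len(K), function(k) {
        rows <- sample(nrow(source), n_per_cohort[k], replace = TRUE)
        source[rows, genes, drop = FALSE]
      })
    }
  })
}

#' Assign causal genes and generating effects for a scenario
#'
#' @param scenario scenario label, `"I"` to `"IV"`.
#' @param p number of genes.
#' @param K number of cohorts.
#' @param seed integer seed.
#' @return List with `beta` (p x K generating coefficients), `truth`
#'   (p x K logical causal indicator), and `causal` — per cohort a list
#'   with `linear` (first five causal genes) and `quadratic` (last five).
#' @export
assign_effects <- function(scenario, p, K, seed) {
  beta <- matrix(0, p, K)
  truth <- matrix(FALSE, p, K)
  causal <- vector("list", K)
  with_seed(seed, {
    if (scenario %in% c("I", "II", "III")) {
      idx <- 1:10
      for (k in seq_len(K)) {
        beta[idx, k] <- switch(scenario,
                               I = 5,
                               II = 2,
                               III = stats::runif(10, 1, 5))
        truth[idx, k] <- TRUE
        causal[[k]] <- list(linear = 1:5, quadratic = 6:10)
      }
    } else if (scenario == "IV") {
      for (k in seq_len(K)) {
        own <- sample(6:p, 5)
        idx <- c(1:5, own)
        beta[idx, k] <- 2
        truth[idx, k] <- TRUE
        causal[[k]] <- list(linear = 1:5, quadratic = own)
      }
    } else {
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    }
  })
  list(beta = beta, truth = truth, causal = causal)
}

#' Generate log event times from the (misspecified) AFT mechanism
#'
#' `log T_i = sum_{j in linear} x_ij b_j + sum_{j in quadratic} x_ij^2 b_j
#'  + eps_i`, `eps ~ N(0, 1)`. The quadratic half of the causal genes makes
#' the generating model richer than the linear AFT being fitted.
#'
#' @param X n x p predictor matrix.
#' @param beta_col length-p generating coefficient vector for this cohort.
#' @param linear_idx,quadratic_idx indices of the linearly and
#'   quadratically acting causal genes.
#' @param seed integer seed for the error draw.
#' @return Length-n vector of log event times.
#' @export
generate_outcomes <- function(X, beta_col, linear_idx, quadratic_idx, seed) {
  n <- nrow(X)
  lp <- numeric(n)
  if (length(linear_idx)) {
    lp <- lp + as.numeric(X[, linear_idx, drop = FALSE] %*%
                            beta_col[linear_idx])
  }
  if (length(quadratic_idx)) {
    lp <- lp + as.numeric(X[, quadratic_idx, drop = FALSE]^2 %*%
                            beta_col[quadratic_idx])
  }
  with_seed(seed, lp + stats::rnorm(n))
}

#' Calibrate exponential censoring to a target rate
#'
#' Finds the exponential rate at which the expected censored fraction
#' `mean_i P(C < T_i) = mean_i (1 - exp(-rate * T_i))` equals `target`
#' (bisection on the closed-form expectation, which is monotone increasing
#' in the rate), then draws censoring times at that rate and forms the
#' observed data.
#'
#' @param log_event_times log-scale event times.
#' @param target target censoring fraction in (0, 1).
#' @param seed integer seed for the censoring draw.
#' @param tol calibration tolerance on the expected fraction (default 0.01).
#' @return List with `rate`, `time` (observed times, original scale),
#'   `delta` (1 = event), and `realized` censoring fraction.
#' @export
calibrate_censoring <- function(log_event_times, target, seed, tol = 0.01) {
  if (target <= 0 || target >= 1) {
    stop("`target` must be in (0, 1)", call. = FALSE)
  }
  Tev <- exp(log_event_times)
  expected_frac <- function(rate) mean(1 - exp(-rate * Tev))
  # bracket the target
  lo <- 0
  hi <- 1 / max(stats::median(Tev), .Machine$double.xmin)
  expansions <- 0
  while (expected_frac(hi) < target) {
    hi <- hi * 2
    expansions <- expansions + 1
    if (expansions > 100) {
      stop("censoring calibration failed to bracket the target rate",
           call. = FALSE)
    }
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_frac(mid) < target) lo <- mid else hi <- mid
  }
  rate <- (lo + hi) / 2
  if (abs(expected_frac(rate) - target) > tol) {
    stop("censoring calibration did not reach the target within tolerance",
         call. = FALSE)
  }
  cens <- with_seed(seed, stats::rexp(length(Tev), rate = rate))
  delta <- as.numeric(Tev <= cens)
  list(rate = rate, time = pmin(Tev, cens), delta = delta,
       realized = mean(delta == 0))
}

#' Simulate a full multi-cohort dataset for one scenario replicate
#'
#' @param scen a [simulation_scenario()].
#' @param source optional predictor pool for real-pool mode.
#' @return A `simulated_dataset`: `data` (canonical `multi_cancer_data`),
#'   `truth`, `beta`, `causal`, `realized_censoring` (per cohort),
#'   `scenario`.
#' @export
simulate_multicancer <- function(scen, source = NULL) {
  stopifnot(inherits(scen, "simulation_scenario"))
  K <- scen$K
  Xs <- generate_predictors(scen$n_per_cohort, scen$p,
                            seed = seed_stream(scen$seed, "predictors"),
                            source = source, rho = scen$rho)
  eff <- assign_effects(scen$scenario, scen$p, K,
                        seed = seed_stream(scen$seed, "effects"))
  gene_ids <- sprintf("g%04d", seq_len(scen$p))
  labels <- names(scen$n_per_cohort)
  if (is.null(labels)) labels <- paste0("C", seq_len(K))
  datasets <- vector("list", K)
  realized <- numeric(K)
  for (k in seq_len(K)) {
    logT <- generate_outcomes(Xs[[k]], eff$beta[, k],
                              eff$causal[[k]]$linear,
                              eff$causal[[k]]$quadratic,
                              seed = seed_stream(scen$seed,
                                                 paste0("noise", k)))
    cen <- calibrate_censoring(logT, scen$censor_target,
                               seed = seed_stream(scen$seed,
                                                  paste0("censor", k)))
    realized[k] <- cen$realized
    colnames(Xs[[k]]) <- gene_ids
    datasets[[k]] <- canonicalize(
      cancer_dataset(Xs[[k]], cen$time, cen$delta,
                     cancer_id = labels[k], gene_ids = gene_ids))
  }
  rownames(eff$truth) <- rownames(eff$beta) <- gene_ids
  structure(
    list(data = multi_cancer_data(datasets), truth = eff$truth,
         beta = eff$beta, causal = eff$causal,
         realized_censoring = stats::setNames(realized, labels),
         scenario = scen),
    class = "simulated_dataset"
  )
}

# Approach table: fusion type and model form per label.
approach_map <- function(label) {
  switch(label,
         A1 = list(method = "marginal", fusion = "magnitude"),
         A2 = list(method = "marginal", fusion = "sign"),
         A3 = list(method = "marginal", fusion = "none"),
         B1 = list(method = "joint", fusion = "magnitude"),
         B2 = list(method = "joint", fusion = "sign"),
         B3 = list(method = "joint", fusion = "none"),
         stop("unknown approach '", label, "'", call. = FALSE))
}

#' Run the simulation study
#'
#' Per replicate: generate a scenario dataset, fit every requested
#' approach with BIC-tuned penalty levels, and score selection against the
#' generating truth. Approaches: A1/A2/A3 marginal with
#' magnitude/sign/no fusion; B1/B2/B3 the joint counterparts.
#'
#' @param scen a [simulation_scenario()].
#' @param approaches subset of `c("A1","A2","A3","B1","B2","B3")`.
#' @param replicates number of Monte-Carlo replicates.
#' @param seed study master seed; each replicate draws its own substream.
#' @param source optional predictor pool (real-pool mode).
#' @param n_sparsity,min_ratio,fusion_multipliers BIC tuning-grid controls
#'   (fused approaches use the nonzero multipliers; A3/B3 use 0).
#' @param tol,max_iter solver controls.
#' @return A `simulation_study` object: `summary` data frame (approach,
#'   mean and Monte-Carlo SE of TPR/FPR/NG), `replicates` (per-replicate
#'   metrics), `scenario`.
#' @export
run_simulation_study <- function(scen,
                                 approaches = c("A1", "A2", "A3",
                                                "B1", "B2", "B3"),
                                 replicates = 10,
                                 seed = 1,
                                 source = NULL,
                                 n_sparsity = 10,
                                 min_ratio = 0.1,
                                 fusion_multipliers = c(0.1, 1, 10),
                                 tol = 1e-4, max_iter = 200) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replicates)) {
    scen_r <- scen
    scen_r$seed <- seed_stream(seed, paste0("rep", r))
    sim <- simulate_multicancer(scen_r, source = source)
    w <- compute_km_weights_all(sim$data)
    for (ap in approaches) {
      am <- approach_map(ap)
      template <- penalty_spec(am$fusion, gamma = 3)
      mult <- if (am$fusion == "none") 0 else fusion_multipliers
      tune <- select_lambdas_bic(sim$data, w, template, method = am$method,
                                 n_sparsity = n_sparsity,
                                 min_ratio = min_ratio,
                                 fusion_multipliers = mult,
                                 tol = tol, max_iter = max_iter)
      fit <- if (am$method == "joint" && !is.null(tune$fit)) tune$fit
             else if (am$method == "joint")
               fit_joint(sim$data, w, tune$selected, tol, max_iter)
             else fit_marginal_all(sim$data, w, tune$selected, tol, max_iter)
      metrics <- identification_metrics(fit$selected, sim$truth)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, approach = ap, tpr = metrics$tpr, fpr = metrics$fpr,
        ng = metrics$ng,
        lambda_sparsity = tune$selected$lambda_sparsity,
        lambda_fusion = tune$selected$lambda_fusion)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$approach), function(df) {
    data.frame(approach = df$approach[1],
               tpr = mean(df$tpr), fpr = mean(df$fpr), ng = mean(df$ng),
               tpr_se = stats::sd(df$tpr) / sqrt(nrow(df)),
               fpr_se = stats::sd(df$fpr) / sqrt(nrow(df)),
               ng_se = stats::sd(df$ng) / sqrt(nrow(df)))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(match(agg$approach, c("A1", "A2", "A3",
                                         "B1", "B2", "B3"))), ]
  structure(list(summary = agg, replicates = reps, scenario = scen,
                 seed = seed),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study: scenario %s, p = %d, K = %d, %d replicates>\n",
              x$scenario$scenario, x$scenario$p, x$scenario$K,
              max(x$replicates$replicate)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
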