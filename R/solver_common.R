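# Internal machinery shared by the marginal and joint solvers.
#
# Both solvers work on the KM-weighted standardized scale: per cohort k the
# response is centered by its weighted mean and every retained column is
# scaled so sum(w * x^2)/n = 1, which makes the loss curvature of each
# coordinate exactly 1. Coefficients are mapped back to the data scale (and
# intercepts recovered) on exit.

# Standardize every cohort; precompute the scalar pieces the CD updates need.
prepare_problem <- function(data, weights) {
  stopifnot(inherits(data, "multi_cancer_data"))
  if (length(weights) != data$K) {
    stop("need one km_weights object per cohort", call. = FALSE)
  }
  cohorts <- vector("list", data$K)
  for (k in seq_len(data$K)) {
    d <- data$datasets[[k]]
    if (!d$canonical) {
      stop("cohort ", d$cancer_id, " is not canonicalized", call. = FALSE)
    }
    std <- weighted_standardize(d, weights[[k]])
    w <- weights[[k]]$w
    n <- d$n
    cohorts[[k]] <- list(
      Xs = std$Xs, yc = std$yc, record = std$record,
      w = w, n = n, keep = std$record$keep,
      # (1/n) X~' W y~  — the loss linear term at beta = 0
      sxy = as.numeric(crossprod(std$Xs, w * std$yc)) / n,
      # (1/(2n)) sum w y~^2 — loss value at beta = 0
      c0 = sum(w * std$yc^2) / (2 * n)
    )
  }
  list(cohorts = cohorts, K = data$K, p = data$p,
       gene_ids = data$gene_ids, cancer_ids = data$cancer_ids)
}

# Fusion contribution to the scalar subproblem for one coordinate.
# eta_row: current coefficients of this gene across cohorts; k: cohort being
# updated; state: frozen fusion state for this gene (list with `s` for
# magnitude — sign vector — or `d` for sign-surrogate denominators).
# Returns c(da, du): additions to the curvature a and linear term u.
fusion_terms <- function(eta_row, k, spec, state) {
  lam <- spec$lambda_fusion
  if (spec$fusion_type == "none" || lam == 0 || length(eta_row) < 2) {
    return(c(0, 0))
  }
  if (spec$fusion_type == "magnitude") {
    s <- as.numeric(state$s[-k] == state$s[k] )
    da <- lam * sum(1 + s)
    du <- 2 * lam * sum(s * eta_row[-k])
  } else {
    dk <- state$d[k]
    da <- 2 * lam * (length(eta_row) - 1) / dk^2
    du <- 2 * lam * sum(eta_row[-k] / state$d[-k]) / dk
  }
  c(da, du)
}

# Frozen fusion state for one gene, taken at the current iterate.
freeze_state <- function(eta_row, spec) {
  if (spec$fusion_type == "magnitude") {
    list(s = sign(eta_row))
  } else if (spec$fusion_type == "sign") {
    list(d = sqrt(eta_row^2 + spec$tau))
  } else {
    list()
  }
}

# Surrogate fusion penalty (lambda/2 prefactor included) under a frozen state;
# quadratic in eta_row, hence minimized exactly by the CD sweep.
surrogate_fusion_value <- function(eta_row, spec, state) {
  lam <- spec$lambda_fusion
  K <- length(eta_row)
  if (spec$fusion_type == "none" || lam == 0 || K < 2) return(0)
  total <- 0
  if (spec$fusion_type == "magnitude") {
    for (k in seq_len(K)) for (kp in seq_len(K)) {
      if (kp == k) next
      s <- as.numeric(state$s[k] == state$s[kp])
      total <- total + (eta_row[k] - s * eta_row[kp])^2
    }
  } else {
    z <- eta_row / state$d
    for (k in seq_len(K)) for (kp in seq_len(K)) {
      if (kp == k) next
      total <- total + (z[k] - z[kp])^2
    }
  }
  lam / 2 * total
}

# Exact (standardized-scale) marginal objective for one gene from scalar
# sufficient statistics. Includes the constant loss term c0 so values are
# comparable with grid/direct evaluations of the full objective.
marginal_objective_scalar <- function(eta_row, sxy_row, keep_row, c0, spec) {
  loss <- sum(c0) - sum(sxy_row[keep_row] * eta_row[keep_row]) +
    0.5 * sum(eta_row[keep_row]^2)
  loss + sum(mcp_value(eta_row, spec$lambda_sparsity, spec$gamma)) +
    fusion_penalty_term(eta_row, spec)
}
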