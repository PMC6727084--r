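# Fixtures and independent oracles shared across test files.

# Random canonical cohort: linear AFT truth with optional censoring.
make_cohort <- function(n, p, seed, beta = NULL, censor = 0.2,
                        cancer_id = "C1", rho = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (rho != 0) {
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * X[, j]
  }
  colnames(X) <- sprintf("g%03d", seq_len(p))
  if (is.null(beta)) beta <- numeric(p)
  logT <- as.numeric(X %*% beta) + rnorm(n)
  if (censor > 0) {
    cen <- calibrate_censoring(logT, censor, seed = seed + 1)
    d <- cancer_dataset(X, cen$time, cen$delta, cancer_id = cancer_id)
  } else {
    d <- cancer_dataset(X, exp(logT), rep(1, n), cancer_id = cancer_id)
  }
  canonicalize(d)
}

make_multi <- function(K, n, p, seed, beta = NULL, censor = 0.2) {
  datasets <- lapply(seq_len(K), function(k) {
    make_cohort(n, p, seed + 100 * k, beta = beta, censor = censor,
                cancer_id = paste0("C", k))
  })
  multi_cancer_data(datasets)
}

# Independent KM-jump oracle: jumps of the Kaplan-Meier estimator of the
# event-time distribution from survival::survfit, mapped back to subjects.
km_jump_oracle <- function(time, delta) {
  fit <- survival::survfit(survival::Surv(time, delta) ~ 1)
  surv <- c(1, fit$surv)
  jump <- -diff(surv)                    # mass at each reported time
  w <- numeric(length(time))
  for (i in seq_along(time)) {
    if (delta[i] == 1) {
      pos <- match(time[i], fit$time)
      # with tied event times, the KM jump at t splits evenly over events at t
      w[i] <- jump[pos] / sum(time == time[i] & delta == 1)
    }
  }
  w
}

# Dense grid-search oracle for the scalar MCP subproblem: coarse scan over
# a window guaranteed to contain the minimizer (|theta*| <= |u| / (a - 1/gamma)
# since the penalty is nondecreasing in |theta|), then a fine refinement.
mcp_prox_grid_oracle <- function(u, a, lambda, gamma) {
  obj <- function(theta) {
    0.5 * a * theta^2 - u * theta + mcp_value(theta, lambda, gamma)
  }
  bound <- abs(u) / (a - 1 / gamma) + 1
  coarse <- seq(-bound, bound, length.out = 40001)
  coarse <- c(coarse, 0)
  t0 <- coarse[which.min(obj(coarse))]
  width <- 2 * bound / 40000
  fine <- seq(t0 - width, t0 + width, length.out = 4001)
  fine <- c(fine, 0)
  fine[which.min(obj(fine))]
}

# Brute-force pairwise concordance oracle: literal double loop over ordered
# pairs with the usable-pair rule.
c_stat_oracle <- function(scores, y, delta) {
  num <- den <- 0
  n <- length(y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (y[i] < y[j] && delta[i] == 1) {
        den <- den + 1
        if (scores[i] < scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Literal re-evaluation of the marginal objective (triple loop, no shared
# code with the implementation).
marginal_objective_oracle <- function(j, eta_row, alpha_row, data, weights,
                                      spec) {
  total <- 0
  for (k in seq_len(data$K)) {
    d <- data$datasets[[k]]
    acc <- 0
    for (i in seq_len(d$n)) {
      acc <- acc + weights[[k]]$w[i] *
        (d$y[i] - alpha_row[k] - d$X[i, j] * eta_row[k])^2
    }
    total <- total + acc / (2 * d$n)
    v <- abs(eta_row[k])
    total <- total + if (v <= spec$gamma * spec$lambda_sparsity) {
      spec$lambda_sparsity * v - v^2 / (2 * spec$gamma)
    } else {
      spec$gamma * spec$lambda_sparsity^2 / 2
    }
  }
  if (spec$fusion_type != "none" && spec$lambda_fusion > 0) {
    K <- data$K
    fus <- 0
    for (k in seq_len(K)) for (kp in seq_len(K)) {
      if (kp == k) next
      if (spec$fusion_type == "magnitude") {
        s <- as.numeric(sign(eta_row[k]) == sign(eta_row[kp]))
        fus <- fus + (eta_row[k] - s * eta_row[kp])^2
      } else {
        fus <- fus + (sign(eta_row[k]) - sign(eta_row[kp]))^2
      }
    }
    total <- total + spec$lambda_fusion / 2 * fus
  }
  unname(total)
}

# Write the bundled two-cohort toy files into a directory; returns paths.
write_toy_cohorts <- function(dir) {
  ext <- system.file("extdata", package = "aftfuse")
  files <- c("expression_A.tsv", "clinical_A.tsv",
             "expression_B.tsv", "clinical_B.tsv", "panel.txt")
  sapply(files, function(f) file.path(ext, f))
}
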