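#' Smallest sparsity level with an all-zero solution
#'
#' With no fusion, the all-zero coefficient matrix is a stationary point of
#' the (standardized-scale) objective exactly when the MCP threshold
#' exceeds every weighted score, so
#' `lambda_max = max_{j,k} |(1/n_k) sum_i w_ik x_ijk y_ik^c|` over retained
#' standardized columns, with `y^c` the KM-weight-centered log time.
#'
#' @param data canonical `multi_cancer_data`.
#' @param weights list of [km_weights()] per cohort.
#' @return Nonnegative scalar; 0 when the design is orthogonal to `y`.
#' @export
lambda_max <- function(data, weights) {
  prep <- prepare_problem(data, weights)
  m <- 0
  for (co in prep$cohorts) {
    if (any(co$keep)) m <- max(m, max(abs(co$sxy[co$keep])))
  }
  m
}

# Candidate (lambda_sparsity, lambda_fusion) grid. Fusion levels are
# relative multipliers of lambda_sparsity; a multiplier of 0 (the
# unintegrated benchmark) is always part of the default grid so fusion is
# only adopted when it helps.
make_lambda_grid <- function(lmax, spec_template,
                             n_sparsity = 25, min_ratio = 0.05,
                             fusion_multipliers = c(0, 0.1, 1, 10),
                             sparsity_values = NULL) {
  if (!is.null(sparsity_values)) {
    ls <- sort(sparsity_values, decreasing = TRUE)
  } else if (lmax <= 0) {
    ls <- 0
  } else {
    ls <- exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_sparsity))
  }
  if (spec_template$fusion_type == "none") fusion_multipliers <- 0
  grid <- expand.grid(lambda_sparsity = ls, fusion_mult = fusion_multipliers,
                      KEEP.OUT.ATTRS = FALSE)
  grid$lambda_fusion <- grid$lambda_sparsity * grid$fusion_mult
  grid
}

# Stratified fold assignment within one cohort: events and censored rows are
# spread across folds separately, so every fold sees events.
stratified_folds <- function(delta, V, seed) {
  n_events <- sum(delta == 1)
  if (n_events < V) {
    stop("too few events (", n_events, ") for ", V,
         "-fold event-stratified splitting", call. = FALSE)
  }
  folds <- integer(length(delta))
  with_seed(seed, {
    for (grp in c(1, 0)) {
      idx <- which(delta == grp)
      if (length(idx)) folds[idx] <- sample(rep_len(seq_len(V), length(idx)))
    }
  })
  folds
}

# KM-weighted normalized squared prediction error on one held-out cohort
# piece; weights recomputed on the held-out rows themselves.
holdout_loss <- function(dataset, scores) {
  w <- compute_km_weights(dataset)$w
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  sum(w * (dataset$y - scores)^2) / sw
}

#' Select penalty levels by stratified cross-validation
#'
#' Folds are drawn within each cohort, stratified by event status. For each
#' candidate `(lambda_sparsity, lambda_fusion)` pair the model is fitted on
#' the training folds and scored on the held-out fold by KM-weighted
#' squared prediction error (held-out KM weights recomputed on the held-out
#' rows). The pair with the lowest mean CV loss wins; ties go to the larger
#' `lambda_sparsity`, then the larger `lambda_fusion`.
#'
#' @param data canonical `multi_cancer_data`.
#' @param weights list of [km_weights()] per cohort (full data).
#' @param spec_template a [penalty_spec()] fixing `fusion_type`, `gamma`,
#'   `tau`; its lambda values are ignored.
#' @param method `"joint"` (default) or `"marginal"`. For the marginal
#'   model the held-out loss is averaged over the p single-gene models.
#' @param V number of folds (default 5).
#' @param seed integer seed controlling the fold draw.
#' @param n_sparsity,min_ratio,fusion_multipliers grid controls, see
#'   Details; defaults: 25 log-spaced sparsity values down to
#'   `0.05 * lambda_max`, fusion multipliers `c(0, 0.1, 1, 10)`.
#' @param sparsity_values optional explicit sparsity levels overriding the
#'   log-spaced grid.
#' @param tol,max_iter passed to the solvers.
#' @return A `tuning_result`: `grid` (with `cv_mean`, `cv_se`), `selected`
#'   (a [penalty_spec()]), `folds`, `lambda_max`, `seed`.
#' @export
select_lambdas_cv <- function(data, weights, spec_template,
                              method = c("joint", "marginal"),
                              V = 5, seed = 1,
                              n_sparsity = 25, min_ratio = 0.05,
                              fusion_multipliers = c(0, 0.1, 1, 10),
                              sparsity_values = NULL,
                              tol = 1e-4, max_iter = 500) {
  method <- match.arg(method)
  if (V < 2) stop("`V` must be at least 2", call. = FALSE)
  lmax <- lambda_max(data, weights)
  grid <- make_lambda_grid(lmax, spec_template, n_sparsity, min_ratio,
                           fusion_multipliers, sparsity_values)
  K <- data$K
  folds <- lapply(seq_len(K), function(k) {
    stratified_folds(data$datasets[[k]]$delta, V,
                     seed_stream(seed, paste0("folds", k)))
  })
  loss_mat <- matrix(NA_real_, nrow(grid), V * K)
  for (v in seq_len(V)) {
    train <- data
    test_sets <- vector("list", K)
    for (k in seq_len(K)) {
      tr_idx <- which(folds[[k]] != v)
      te_idx <- which(folds[[k]] == v)
      train$datasets[[k]] <- subset_rows(data$datasets[[k]], tr_idx)
      test_sets[[k]] <- subset_rows(data$datasets[[k]], te_idx)
    }
    w_train <- compute_km_weights_all(train)
    prep_train <- prepare_problem(train, w_train)
    gram_train <- if (method == "joint") joint_gram(prep_train)
    for (mult in unique(grid$fusion_mult)) {
      rows <- which(grid$fusion_mult == mult)
      rows <- rows[order(-grid$lambda_sparsity[rows])]
      init <- NULL
      for (g in rows) {
        sp <- penalty_spec(spec_template$fusion_type,
                           lambda_sparsity = grid$lambda_sparsity[g],
                           lambda_fusion = grid$lambda_fusion[g],
                           gamma = spec_template$gamma,
                           tau = spec_template$tau)
        if (method == "joint") {
          fit <- fit_joint(train, w_train, sp, tol = tol,
                           max_iter = max_iter, init = init,
                           .prep = prep_train, .gram = gram_train)
          init <- fit$beta_std
          for (k in seq_len(K)) {
            sc <- predict_survival_scores(fit, test_sets[[k]],
                                          data$cancer_ids[k])
            loss_mat[g, (v - 1) * K + k] <- holdout_loss(test_sets[[k]], sc)
          }
        } else {
          fit <- fit_marginal_all(train, w_train, sp, tol = tol,
                                  max_iter = max_iter, .prep = prep_train)
          for (k in seq_len(K)) {
            te <- test_sets[[k]]
            per_gene <- vapply(seq_len(data$p), function(j) {
              sc <- fit$alpha[j, k] + te$X[, j] * fit$eta[j, k]
              holdout_loss(te, sc)
            }, numeric(1))
            loss_mat[g, (v - 1) * K + k] <- mean(per_gene, na.rm = TRUE)
          }
        }
      }
    }
  }
  grid$cv_mean <- rowMeans(loss_mat, na.rm = TRUE)
  grid$cv_se <- apply(loss_mat, 1, function(x) {
    x <- x[!is.na(x)]
    stats::sd(x) / sqrt(length(x))
  })
  sel <- pick_best(grid, grid$cv_mean)
  structure(
    list(grid = grid,
         selected = penalty_spec(spec_template$fusion_type,
                                 lambda_sparsity = grid$lambda_sparsity[sel],
                                 lambda_fusion = grid$lambda_fusion[sel],
                                 gamma = spec_template$gamma,
                                 tau = spec_template$tau),
         folds = folds, lambda_max = lmax, seed = seed, method = method),
    class = "tuning_result"
  )
}

# Minimal-score row with the documented tie rule: larger lambda_sparsity,
# then larger lambda_fusion.
pick_best <- function(grid, score) {
  tol <- 1e-12 * (1 + abs(min(score, na.rm = TRUE)))
  cand <- which(score <= min(score, na.rm = TRUE) + tol)
  cand[order(-grid$lambda_sparsity[cand], -grid$lambda_fusion[cand])][1]
}

#' Select penalty levels by a BIC-type criterion
#'
#' Fast alternative to cross-validation used by the simulation study: fit
#' each candidate pair on the full data and score it with
#' `sum_k n_k log(weighted RSS_k / sum(w_k)) + log(n_k) df_k`, where `df_k`
#' counts nonzero coefficients in cohort k (for the marginal model the
#' per-gene models are summed). Ties resolved as in [select_lambdas_cv()].
#'
#' @inheritParams select_lambdas_cv
#' @return A `tuning_result` with `grid` (including `bic`), `selected`,
#'   `lambda_max`. For `method = "joint"` the fit at the selected pair is
#'   attached as `fit`.
#' @export
select_lambdas_bic <- function(data, weights, spec_template,
                               method = c("joint", "marginal"),
                               n_sparsity = 25, min_ratio = 0.05,
                               fusion_multipliers = c(0, 0.1, 1, 10),
                               tol = 1e-4, max_iter = 500) {
  method <- match.arg(method)
  prep <- prepare_problem(data, weights)
  gram <- if (method == "joint") joint_gram(prep)
  lmax <- max(0, vapply(prep$cohorts, function(co) {
    if (any(co$keep)) max(abs(co$sxy[co$keep])) else 0
  }, numeric(1)))
  grid <- make_lambda_grid(lmax, spec_template, n_sparsity, min_ratio,
                           fusion_multipliers)
  K <- data$K
  n_k <- vapply(data$datasets, `[[`, numeric(1), "n")
  sw_k <- vapply(weights, function(w) sum(w$w), numeric(1))
  # per-cohort scalar pieces for the marginal weighted RSS:
  # RSS_jk = 2 n c0 - 2 n sxy eta + n eta^2 on the standardized scale
  sxy_mat <- vapply(prep$cohorts, `[[`, numeric(data$p), "sxy")
  c0_k <- vapply(prep$cohorts, `[[`, numeric(1), "c0")
  bic <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (mult in unique(grid$fusion_mult)) {
    rows <- which(grid$fusion_mult == mult)
    rows <- rows[order(-grid$lambda_sparsity[rows])]
    init <- NULL
    for (g in rows) {
      sp <- penalty_spec(spec_template$fusion_type,
                         lambda_sparsity = grid$lambda_sparsity[g],
                         lambda_fusion = grid$lambda_fusion[g],
                         gamma = spec_template$gamma,
                         tau = spec_template$tau)
      if (method == "joint") {
        fit <- fit_joint(data, weights, sp, tol = tol, max_iter = max_iter,
                         init = init, .prep = prep, .gram = gram)
        init <- fit$beta_std
        val <- 0
        for (k in seq_len(K)) {
          d <- data$datasets[[k]]
          r <- d$y - fit$alpha[k] - as.numeric(d$X %*% fit$beta[, k])
          rss <- sum(weights[[k]]$w * r^2)
          df <- sum(fit$selected[, k])
          val <- val + n_k[k] * log(max(rss / sw_k[k], 1e-300)) +
            log(n_k[k]) * df
        }
      } else {
        fit <- fit_marginal_all(data, weights, sp, tol = tol,
                                max_iter = max_iter, .prep = prep)
        val <- 0
        for (k in seq_len(K)) {
          eta <- fit$eta_std[, k]
          rss <- n_k[k] * (2 * c0_k[k] - 2 * sxy_mat[, k] * eta + eta^2)
          val <- val + sum(n_k[k] * log(pmax(rss / sw_k[k], 1e-300)) +
                             log(n_k[k]) * (eta != 0))
        }
      }
      bic[g] <- val
      fits[[g]] <- fit
    }
  }
  grid$bic <- bic
  sel <- pick_best(grid, bic)
  structure(
    list(grid = grid,
         selected = penalty_spec(spec_template$fusion_type,
                                 lambda_sparsity = grid$lambda_sparsity[sel],
                                 lambda_fusion = grid$lambda_fusion[sel],
                                 gamma = spec_template$gamma,
                                 tau = spec_template$tau),
         fit = fits[[sel]], lambda_max = lmax, method = method),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result (", x$method, "): selected lambda_sparsity = ",
      format(x$selected$lambda_sparsity), ", lambda_fusion = ",
      format(x$selected$lambda_fusion), ">\n", sep = "")
  invisible(x)
}

#' Write a tuning summary as a tab-separated table
#' @param result a `tuning_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tuning_table <- function(result, path) {
  utils::write.table(result$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
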