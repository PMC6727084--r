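#' Marginal integrative objective for one gene (data scale)
#'
#' Evaluates, for gene `j`, the weighted penalized marginal objective
#'
#'   sum_k (1/(2 n_k)) sum_i w_ik (y_ik - alpha_jk - x_ijk eta_jk)^2
#'     + sum_k mcp_value(eta_jk) + (lambda_fusion/2) * fusion terms,
#'
#' at the supplied coefficients, on whatever scale the data and coefficients
#' are given. Used directly for oracle/grid checks.
#'
#' @param gene_index integer index of the gene (column of each `X`).
#' @param eta_row,alpha_row length-K slope and intercept vectors.
#' @param data a canonical `multi_cancer_data`.
#' @param weights list of [km_weights()] per cohort.
#' @param spec a [penalty_spec()].
#' @return Nonnegative objective value.
#' @export
marginal_objective <- function(gene_index, eta_row, alpha_row, data, weights,
                               spec) {
  stopifnot(inherits(data, "multi_cancer_data"))
  K <- data$K
  if (length(eta_row) != K || length(alpha_row) != K) {
    stop("`eta_row` and `alpha_row` must have one entry per cohort",
         call. = FALSE)
  }
  loss <- 0
  for (k in seq_len(K)) {
    d <- data$datasets[[k]]
    r <- d$y - alpha_row[k] - d$X[, gene_index] * eta_row[k]
    loss <- loss + sum(weights[[k]]$w * r^2) / (2 * d$n)
  }
  loss + sum(mcp_value(eta_row, spec$lambda_sparsity, spec$gamma)) +
    fusion_penalty_term(eta_row, spec)
}

# Coordinate descent on the standardized scalar statistics of one gene.
# sxy: length-K weighted inner products; keep: which cohorts retain the gene.
# Returns the standardized eta row plus diagnostics, including per-sweep
# frozen-surrogate objective values before and after each sweep.
cd_marginal_gene <- function(sxy, keep, c0, spec, tol, max_iter, init = NULL) {
  K <- length(sxy)
  eta <- if (is.null(init)) numeric(K) else init
  eta[!keep] <- 0
  lam1 <- spec$lambda_sparsity
  fuse <- spec$fusion_type != "none" && spec$lambda_fusion > 0 && K > 1
  surr_start <- surr_end <- numeric(0)
  converged <- FALSE
  it <- 0
  surrogate_obj <- function(e, state) {
    loss <- sum(c0) - sum(sxy[keep] * e[keep]) + 0.5 * sum(e[keep]^2)
    loss + sum(mcp_value(e, lam1, spec$gamma)) +
      surrogate_fusion_value(e, spec, state)
  }
  lam2 <- spec$lambda_fusion
  gamma <- spec$gamma
  magnitude <- spec$fusion_type == "magnitude"
  thr_mult <- gamma * lam1
  Km1 <- K - 1
  while (it < max_iter) {
    it <- it + 1
    state <- freeze_state(eta, spec)
    if (fuse) surr_start <- c(surr_start, surrogate_obj(eta, state))
    max_change <- 0
    for (k in seq_len(K)) {
      if (!keep[k]) next
      old <- eta[k]
      a <- 1
      u <- sxy[k]
      if (fuse) {
        if (magnitude) {
          s <- state$s == state$s[k]   # includes k itself
          a <- a + lam2 * (Km1 + sum(s) - 1)
          u <- u + 2 * lam2 * (sum(eta[s]) - old)
        } else {
          d <- state$d
          a <- a + 2 * lam2 * Km1 / d[k]^2
          u <- u + 2 * lam2 * (sum(eta / d) - old / d[k]) / d[k]
        }
      }
      au <- abs(u)
      new <- if (au <= a * thr_mult) {
        s0 <- au - lam1
        if (s0 > 0) sign(u) * s0 / (a - 1 / gamma) else 0
      } else {
        u / a
      }
      max_change <- max(max_change, abs(new - old))
      eta[k] <- new
    }
    if (fuse) surr_end <- c(surr_end, surrogate_obj(eta, state))
    if (max_change < tol * (1 + max(abs(eta)))) {
      converged <- TRUE
      break
    }
  }
  list(eta = eta, iterations = it, converged = converged,
       surrogate_start = surr_start, surrogate_end = surr_end)
}

#' Fit the marginal integrative model for one gene
#'
#' Coordinate descent over the K cohort coefficients of a single gene on
#' the KM-weighted standardized scale. Each scalar subproblem (loss
#' curvature plus frozen fusion quadratic) is solved exactly by
#' [mcp_prox()]; the fusion state (sign-agreement indicators, or smoothed
#' sign denominators) is refrozen once per sweep, so each sweep minimizes a
#' fixed quadratic-plus-MCP surrogate. Several deterministic starting
#' points are tried (all-zero, the unpenalized per-cohort fit, and the
#' fusion-free MCP fit) and the candidate with the lowest exact objective
#' is returned — the exact objective is nonconvex in the sign indicators,
#' so a single start can land in an inferior fixed point.
#'
#' @param gene_index gene to fit (column index).
#' @param data canonical `multi_cancer_data`.
#' @param weights list of [km_weights()] per cohort.
#' @param spec a [penalty_spec()].
#' @param tol relative coefficient-change convergence tolerance.
#' @param max_iter maximum CD sweeps per start.
#' @return List with `eta_row` and `alpha_row` (data scale, length K),
#'   `eta_std`, `objective` (exact standardized-scale value), `iterations`,
#'   `converged`.
#' @export
fit_marginal_gene <- function(gene_index, data, weights, spec,
                              tol = 1e-4, max_iter = 500) {
  prep <- prepare_problem(data, weights)
  fit <- fit_marginal_gene_prepped(gene_index, prep, spec, tol, max_iter)
  finalize_marginal_gene(fit, gene_index, prep)
}

# Core per-gene fit on a prepared problem (shared with fit_marginal_all).
fit_marginal_gene_prepped <- function(j, prep, spec, tol, max_iter) {
  K <- prep$K
  sxy <- vapply(prep$cohorts, function(co) co$sxy[j], numeric(1))
  keep <- vapply(prep$cohorts, function(co) co$keep[j], logical(1))
  c0 <- vapply(prep$cohorts, `[[`, numeric(1), "c0")
  inits <- list(numeric(K))
  if (spec$fusion_type != "none" && spec$lambda_fusion > 0) {
    inits <- c(inits, list(ifelse(keep, sxy, 0)),
               list(mcp_prox(ifelse(keep, sxy, 0), 1,
                             spec$lambda_sparsity, spec$gamma)))
  }
  best <- NULL
  best_obj <- Inf
  for (init in inits) {
    res <- cd_marginal_gene(sxy, keep, c0, spec, tol, max_iter, init = init)
    obj <- marginal_objective_scalar(res$eta, sxy, keep, c0, spec)
    if (obj < best_obj - 1e-12) {
      best <- res
      best_obj <- obj
    }
  }
  best$objective <- best_obj
  best$sxy <- sxy
  best$keep <- keep
  best
}

# Map a standardized per-gene fit back to the data scale.
finalize_marginal_gene <- function(fit, j, prep) {
  K <- prep$K
  eta_row <- alpha_row <- numeric(K)
  for (k in seq_len(K)) {
    rec <- prep$cohorts[[k]]$record
    eta_k <- if (rec$keep[j]) fit$eta[k] / rec$x_scale[j] else 0
    eta_row[k] <- eta_k
    alpha_row[k] <- rec$y_center - eta_k * rec$x_center[j]
  }
  list(eta_row = eta_row, alpha_row = alpha_row, eta_std = fit$eta,
       objective = fit$objective, iterations = fit$iterations,
       converged = fit$converged,
       surrogate_start = fit$surrogate_start,
       surrogate_end = fit$surrogate_end)
}

#' Fit the marginal integrative model for all genes
#'
#' Applies [fit_marginal_gene()] independently to each of the p genes with
#' the same penalty levels (the marginal objectives are separate problems,
#' one per gene, sharing lambda values). Genes with a nonzero standardized
#' slope in cohort k are flagged as identified for that cohort.
#'
#' @inheritParams fit_marginal_gene
#' @param .prep internal: precomputed [prepare_problem()] object reused
#'   across a lambda path.
#' @return A `marginal_fit` object: `eta` and `alpha` (p x K, data scale),
#'   `eta_std` (p x K), `selected` (p x K logical), `objective` (length p),
#'   `iterations`, `converged`, `spec`, `gene_ids`, `cancer_ids`.
#' @export
fit_marginal_all <- function(data, weights, spec, tol = 1e-4, max_iter = 500,
                             .prep = NULL) {
  prep <- if (is.null(.prep)) prepare_problem(data, weights) else .prep
  p <- prep$p
  K <- prep$K
  eta <- alpha <- eta_std <- matrix(0, p, K,
                                    dimnames = list(prep$gene_ids,
                                                    prep$cancer_ids))
  objective <- numeric(p)
  iterations <- integer(p)
  converged <- logical(p)
  for (j in seq_len(p)) {
    fit <- fit_marginal_gene_prepped(j, prep, spec, tol, max_iter)
    fin <- finalize_marginal_gene(fit, j, prep)
    eta[j, ] <- fin$eta_row
    alpha[j, ] <- fin$alpha_row
    eta_std[j, ] <- fin$eta_std
    objective[j] <- fin$objective
    iterations[j] <- fin$iterations
    converged[j] <- fin$converged
  }
  structure(
    list(eta = eta, alpha = alpha, eta_std = eta_std,
         selected = eta_std != 0, objective = objective,
         iterations = iterations, converged = converged, spec = spec,
         gene_ids = prep$gene_ids, cancer_ids = prep$cancer_ids),
    class = "marginal_fit"
  )
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat(sprintf(
    "<marginal_fit: %d genes x %d cohorts, %d nonzero coefficients>\n",
    nrow(x$eta), ncol(x$eta), sum(x$selected)))
  invisible(x)
}

#' Write a genes x cohorts coefficient table plus JSON diagnostics
#'
#' @param fit a `marginal_fit` or `joint_fit`.
#' @param path output TSV path; a `.json` sidecar with convergence
#'   diagnostics is written next to it.
#' @return Invisibly, the paths written.
#' @export
write_coefficient_table <- function(fit, path) {
  coefs <- if (inherits(fit, "marginal_fit")) fit$eta else fit$beta
  df <- data.frame(gene = rownames(coefs), coefs, check.names = FALSE)
  if (inherits(fit, "joint_fit")) {
    df <- rbind(data.frame(gene = "(Intercept)", t(fit$alpha),
                           check.names = FALSE), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "", path)
  side <- paste0(side, ".json")
  diag <- list(
    model = class(fit)[1],
    lambda_sparsity = fit$spec$lambda_sparsity,
    lambda_fusion = fit$spec$lambda_fusion,
    fusion_type = fit$spec$fusion_type,
    gamma = fit$spec$gamma,
    n_selected = sum(if (inherits(fit, "marginal_fit")) fit$selected
                     else fit$beta_std != 0),
    converged = all(fit$converged)
  )
  jsonlite::write_json(diag, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, side))
}
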