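#' Penalty specification for integrative AFT fitting
#'
#' Bundles the tuning parameters shared by the marginal and joint solvers:
#' the MCP sparsity level, the fusion (similarity) level, the MCP concavity
#' parameter, and the smoothing constant used by the sign-fusion surrogate.
#'
#' @param fusion_type one of `"magnitude"`, `"sign"`, `"none"`. With
#'   `"none"` the fusion weight is ignored and each cohort is fitted
#'   separately (the unintegrated benchmark).
#' @param lambda_sparsity nonnegative MCP sparsity tuning parameter
#'   (lambda1 in the marginal model, lambda3 in the joint model).
#' @param lambda_fusion nonnegative fusion tuning parameter (lambda2 /
#'   lambda4). Ignored when `fusion_type = "none"`.
#' @param gamma MCP concavity parameter, must exceed 1. Default 3, the
#'   common choice for MCP on standardized designs.
#' @param tau positive smoothing constant for the sign surrogate
#'   `v / sqrt(v^2 + tau)`; on the standardized coefficient scale.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(fusion_type = c("magnitude", "sign", "none"),
                         lambda_sparsity = 0,
                         lambda_fusion = 0,
                         gamma = 3,
                         tau = 1e-2) {
  fusion_type <- match.arg(fusion_type)
  if (!is.numeric(lambda_sparsity) || length(lambda_sparsity) != 1L ||
      is.na(lambda_sparsity) || lambda_sparsity < 0) {
    stop("`lambda_sparsity` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(lambda_fusion) || length(lambda_fusion) != 1L ||
      is.na(lambda_fusion) || lambda_fusion < 0) {
    stop("`lambda_fusion` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 1) {
    stop("`gamma` must be a single number greater than 1", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  structure(
    list(fusion_type = fusion_type,
         lambda_sparsity = as.numeric(lambda_sparsity),
         lambda_fusion = if (fusion_type == "none") 0 else as.numeric(lambda_fusion),
         gamma = as.numeric(gamma),
         tau = as.numeric(tau)),
    class = "penalty_spec"
  )
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat("Penalty spec: MCP(lambda =", format(x$lambda_sparsity),
      ", gamma =", format(x$gamma), ")")
  if (x$fusion_type == "none") {
    cat(", no fusion\n")
  } else {
    cat(", ", x$fusion_type, " fusion (lambda =", format(x$lambda_fusion),
        ", tau =", format(x$tau), ")\n", sep = "")
  }
  invisible(x)
}

#' Minimax concave penalty (MCP) value
#'
#' `rho(v; lambda, gamma) = lambda * integral_0^|v| (1 - x/(lambda*gamma))_+ dx`,
#' i.e. `lambda*|v| - v^2/(2*gamma)` for `|v| <= gamma*lambda` and the
#' saturated value `gamma*lambda^2/2` beyond.
#'
#' @param v coefficient value(s); vectorized.
#' @param lambda nonnegative penalty level.
#' @param gamma concavity parameter (> 1).
#' @return Penalty value(s), same length as `v`.
#' @export
mcp_value <- function(v, lambda, gamma = 3) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  if (gamma <= 1) stop("`gamma` must exceed 1", call. = FALSE)
  av <- abs(v)
  ifelse(av <= gamma * lambda,
         lambda * av - av^2 / (2 * gamma),
         gamma * lambda^2 / 2)
}

#' Scalar MCP proximal (coordinate-update) operator
#'
#' Exact minimizer of `0.5*a*theta^2 - u*theta + mcp_value(theta, lambda, gamma)`.
#' This is the scalar subproblem each coordinate-descent step solves; `a` is
#' the curvature of the quadratic part (loss plus any frozen fusion terms) and
#' `u` its linear coefficient. Requires `a > 1/gamma` so the subproblem is
#' strictly convex.
#'
#' @param u linear term(s); vectorized.
#' @param a quadratic curvature (scalar or same length as `u`).
#' @param lambda nonnegative MCP level.
#' @param gamma concavity parameter (> 1).
#' @return The minimizing theta value(s).
#' @export
mcp_prox <- function(u, a, lambda, gamma = 3) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  if (gamma <= 1) stop("`gamma` must exceed 1", call. = FALSE)
  if (any(a <= 1 / gamma)) {
    stop("coordinate curvature a <= 1/gamma: scalar subproblem not convex; ",
         "increase `gamma` or rescale the design", call. = FALSE)
  }
  soft <- sign(u) * pmax(abs(u) - lambda, 0)
  ifelse(abs(u) <= a * gamma * lambda, soft / (a - 1 / gamma), u / a)
}

#' Magnitude-based fusion penalty for one gene across cohorts
#'
#' Sum over ordered cohort pairs (k, k') of
#' `(eta_k - s_kk' * eta_k')^2` where `s_kk' = 1` if `sign(eta_k) ==
#' sign(eta_k')` and 0 otherwise (`sign(0) = 0`). Promotes quantitative
#' similarity: same-signed effects are pulled toward equal magnitude, while
#' opposite-signed effects are individually shrunk.
#'
#' @param coef_row numeric vector of one gene's coefficients across K cohorts.
#' @return Nonnegative penalty value.
#' @export
magnitude_fusion_value <- function(coef_row) {
  K <- length(coef_row)
  if (K < 2) return(0)
  sg <- sign(coef_row)
  total <- 0
  for (k in seq_len(K)) {
    for (kp in seq_len(K)) {
      if (kp == k) next
      s <- as.numeric(sg[k] == sg[kp])
      total <- total + (coef_row[k] - s * coef_row[kp])^2
    }
  }
  total
}

#' Sign-based fusion penalty for one gene across cohorts
#'
#' Sum over ordered cohort pairs (k, k') of
#' `(sign(eta_k) - sign(eta_k'))^2` with `sign(0) = 0`. Promotes qualitative
#' similarity (same direction of effect) and is invariant to positive
#' rescaling of the coefficients.
#'
#' @inheritParams magnitude_fusion_value
#' @return Nonnegative penalty value.
#' @export
sign_fusion_value <- function(coef_row) {
  K <- length(coef_row)
  if (K < 2) return(0)
  sg <- sign(coef_row)
  total <- 0
  for (k in seq_len(K)) {
    for (kp in seq_len(K)) {
      if (kp == k) next
      total <- total + (sg[k] - sg[kp])^2
    }
  }
  total
}

#' Smoothed sign surrogate
#'
#' `v / sqrt(v^2 + tau)`: a differentiable stand-in for `sign(v)` used when
#' optimizing the (discontinuous) sign-fusion penalty. Odd in `v`, bounded in
#' (-1, 1), and approaching `sign(v)` as `tau -> 0`.
#'
#' @param v numeric value(s).
#' @param tau positive smoothing constant.
#' @return Smoothed sign value(s) in (-1, 1).
#' @export
smooth_sign <- function(v, tau) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  v / sqrt(v^2 + tau)
}

# Fusion penalty value dispatched on the spec; eta_row is one gene's
# coefficients across cohorts. Returns the (lambda_fusion/2) * sum term
# of the objective.
fusion_penalty_term <- function(coef_row, spec) {
  if (spec$fusion_type == "none" || spec$lambda_fusion == 0) return(0)
  val <- switch(spec$fusion_type,
                magnitude = magnitude_fusion_value(coef_row),
                sign = sign_fusion_value(coef_row))
  spec$lambda_fusion / 2 * val
}
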