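#' Relative overlap (Jaccard index) of two gene sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty (with a
#' warning), since two empty selections carry no overlap information.
#'
#' @param setA,setB character (or other atomic) vectors of selected genes.
#' @return Value in \code{[0, 1]}.
#' @export
relative_overlap <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  u <- union(setA, setB)
  if (length(u) == 0) {
    warning("both gene sets are empty; relative overlap defined as 0")
    return(0)
  }
  length(intersect(setA, setB)) / length(u)
}

#' Relative Euclidean distance between two coefficient vectors
#'
#' `sum_j (a_j - b_j)^2 / sqrt(sum_j a_j^2 * sum_j b_j^2)`: 0 iff the
#' vectors are identical, 2 for equal-norm orthogonal vectors; smaller
#' means the two cohorts' estimated effects are more similar.
#'
#' @param coefA,coefB numeric vectors of equal length, not both all-zero.
#' @return Nonnegative scalar.
#' @export
relative_euclidean_distance <- function(coefA, coefB) {
  if (length(coefA) != length(coefB)) {
    stop("coefficient vectors must have equal length", call. = FALSE)
  }
  na2 <- sum(coefA^2)
  nb2 <- sum(coefB^2)
  if (na2 == 0 || nb2 == 0) {
    stop("relative Euclidean distance undefined for an all-zero vector",
         call. = FALSE)
  }
  sum((coefA - coefB)^2) / sqrt(na2 * nb2)
}

#' Pairwise evaluation matrices for a fitted model
#'
#' Computes the K x K relative-overlap matrix of the selected gene sets and
#' the K x K relative Euclidean distance matrix of the coefficient columns.
#'
#' @param fit a `marginal_fit` or `joint_fit`.
#' @return List with `rol` and `dist` matrices (cohort labels on both
#'   dimensions); a distance entry is `NA` when a cohort has an all-zero
#'   coefficient vector.
#' @export
evaluate_similarity <- function(fit) {
  coefs <- if (inherits(fit, "marginal_fit")) fit$eta else fit$beta
  sel <- if (inherits(fit, "marginal_fit")) fit$selected else fit$beta_std != 0
  K <- ncol(coefs)
  ids <- colnames(coefs)
  rol <- matrix(1, K, K, dimnames = list(ids, ids))
  dst <- matrix(0, K, K, dimnames = list(ids, ids))
  for (k in seq_len(K)) {
    for (kp in seq_len(K)) {
      if (kp <= k) next
      rol[k, kp] <- rol[kp, k] <-
        relative_overlap(rownames(coefs)[sel[, k]], rownames(coefs)[sel[, kp]])
      d <- if (sum(coefs[, k]^2) == 0 || sum(coefs[, kp]^2) == 0) NA_real_
           else relative_euclidean_distance(coefs[, k], coefs[, kp])
      dst[k, kp] <- dst[kp, k] <- d
    }
  }
  list(rol = rol, dist = dst)
}

#' Average-linkage hierarchical clustering of cohorts
#'
#' Agglomerative clustering of the cohorts from a symmetric nonnegative
#' distance matrix (zero diagonal), average linkage. Merge order is
#' deterministic; at tied heights `stats::hclust` merges the
#' lowest-indexed admissible pair first.
#'
#' @param distance_matrix symmetric K x K matrix, zero diagonal.
#' @return An object of class `hclust` (merge history + heights).
#' @export
cluster_cancers <- function(distance_matrix) {
  distance_matrix <- as.matrix(distance_matrix)
  if (nrow(distance_matrix) != ncol(distance_matrix) ||
      any(abs(distance_matrix - t(distance_matrix)) > 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(distance_matrix) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(distance_matrix < 0)) {
    stop("distances must be nonnegative", call. = FALSE)
  }
  stats::hclust(stats::as.dist(distance_matrix), method = "average")
}

#' Censoring-aware concordance (C-statistic)
#'
#' Harrell-type pairwise concordance for predicted log survival times:
#' over usable pairs (i, j) with `y_i < y_j` and `delta_i = 1`, the
#' fraction where `score_i < score_j`, score ties counting 1/2. A larger
#' predicted score means longer predicted survival, so concordance means
#' the earlier death has the smaller score. An IPCW (Uno-type) variant,
#' which reweights usable pairs by the inverse squared Kaplan-Meier
#' estimate of the censoring distribution at the earlier time, is
#' available via `method = "ipcw"`.
#'
#' @param scores predicted log survival times.
#' @param y observed log times.
#' @param delta event indicators (1 = death).
#' @param method `"harrell"` (default) or `"ipcw"`.
#' @return List with `c` (raw value in \code{[0, 1]}), `c_clipped`
#'   (clipped to \code{[0.5, 1]} as reported in summary tables), and
#'   `n_pairs` (number, or total weight, of usable pairs).
#' @export
c_statistic <- function(scores, y, delta, method = c("harrell", "ipcw")) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(length(scores) == n, length(delta) == n)
  if (method == "ipcw") {
    gw <- censoring_km(y, delta)
  }
  num <- den <- 0
  for (i in seq_len(n)) {
    if (delta[i] != 1) next
    comp <- which(y > y[i])
    if (!length(comp)) next
    wt <- if (method == "ipcw") 1 / gw[i]^2 else 1
    agree <- sum(scores[i] < scores[comp]) + 0.5 * sum(scores[i] == scores[comp])
    num <- num + wt * agree
    den <- den + wt * length(comp)
  }
  if (den == 0) {
    stop("no usable pairs: concordance undefined", call. = FALSE)
  }
  cval <- num / den
  list(c = cval, c_clipped = min(max(cval, 0.5), 1), n_pairs = den)
}

# Left-continuous Kaplan-Meier estimate of the censoring survival function
# G(t-) evaluated at each subject's own time (for IPCW weights).
censoring_km <- function(y, delta) {
  # For the censoring distribution the roles flip: delta = 0 is the event;
  # at tied times deaths are taken to precede censorings.
  ord <- order(y, -delta)
  ys <- y[ord]
  ev <- 1 - delta[ord]
  n <- length(ys)
  at_risk <- n - seq_len(n) + 1
  surv_step <- cumprod(1 - ev / at_risk)
  # G(t-): value just before each subject's own time
  g <- vapply(y, function(t) {
    prior <- which(ys < t)
    if (!length(prior)) 1 else surv_step[max(prior)]
  }, numeric(1))
  pmax(g, 1e-8)
}

#' Variable-selection metrics against a known truth
#'
#' `TPR = mean_k TP_k / |S_k|`, `FPR = mean_k FP_k / (p - |S_k|)` (averaged
#' per cohort then across cohorts), and `NG` = number of genes that are
#' causal in every cohort and selected in every cohort.
#'
#' @param selected p x K logical/0-1 matrix of selected genes.
#' @param truth p x K logical/0-1 matrix of truly causal genes.
#' @return List with `tpr`, `fpr`, `ng`.
#' @export
identification_metrics <- function(selected, truth) {
  selected <- as.matrix(selected) != 0
  truth <- as.matrix(truth) != 0
  if (!all(dim(selected) == dim(truth))) {
    stop("`selected` and `truth` must have identical dimensions",
         call. = FALSE)
  }
  p <- nrow(truth)
  K <- ncol(truth)
  if (any(colSums(truth) == 0)) {
    stop("every cohort must have at least one causal gene in `truth`",
         call. = FALSE)
  }
  tpr_k <- fpr_k <- numeric(K)
  for (k in seq_len(K)) {
    s_k <- truth[, k]
    tpr_k[k] <- sum(selected[s_k, k]) / sum(s_k)
    fpr_k[k] <- if (p - sum(s_k) > 0) sum(selected[!s_k, k]) / (p - sum(s_k))
                else 0
  }
  common_causal <- rowSums(truth) == K
  ng <- sum(common_causal & rowSums(selected) == K)
  list(tpr = mean(tpr_k), fpr = mean(fpr_k), ng = ng)
}

#' Write evaluation matrices and a JSON summary
#'
#' @param sim a list as returned by [evaluate_similarity()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_evaluation_report <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rol_path <- file.path(dir, "relative_overlap.tsv")
  dst_path <- file.path(dir, "relative_distance.tsv")
  utils::write.table(sim$rol, rol_path, sep = "\t", quote = FALSE)
  utils::write.table(sim$dist, dst_path, sep = "\t", quote = FALSE)
  js <- file.path(dir, "summary.json")
  off <- upper.tri(sim$rol)
  jsonlite::write_json(
    list(mean_rol = mean(sim$rol[off], na.rm = TRUE),
         mean_distance = mean(sim$dist[off], na.rm = TRUE)),
    js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(rol_path, dst_path, js))
}
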