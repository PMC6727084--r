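#' Construct a single-cohort dataset
#'
#' Holds one cancer cohort's expression matrix together with observed
#' survival times and event indicators. Times are kept on their original
#' (months) scale until [canonicalize()] log-transforms and sorts them.
#'
#' @param X n x p numeric expression matrix (samples in rows).
#' @param time length-n positive observed times in months (or, after
#'   canonicalization, log-times stored in `y`).
#' @param status length-n event indicator, 1 = death observed, 0 = censored.
#' @param cancer_id short cohort label, e.g. `"BRCA"`.
#' @param gene_ids character vector of p gene symbols (defaults to
#'   `colnames(X)`).
#' @return A `cancer_dataset` object with fields `cancer_id`, `gene_ids`,
#'   `X`, `y` (times; log scale once canonical), `delta`, `n`, `p`, and a
#'   `canonical` flag.
#' @export
cancer_dataset <- function(X, time, status, cancer_id = "cohort",
                           gene_ids = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(X)))
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- nrow(X)
  if (length(time) != n || length(status) != n) {
    stop("`time` and `status` must have one entry per row of `X`", call. = FALSE)
  }
  if (anyNA(X)) stop("missing values in expression matrix for cohort ",
                     cancer_id, call. = FALSE)
  if (anyNA(time) || anyNA(status)) {
    stop("missing survival time or status in cohort ", cancer_id, call. = FALSE)
  }
  if (!all(status %in% c(0, 1))) {
    stop("`status` must be coded 0/1", call. = FALSE)
  }
  if (length(gene_ids) != ncol(X)) {
    stop("`gene_ids` length must match ncol(X)", call. = FALSE)
  }
  colnames(X) <- gene_ids
  structure(
    list(cancer_id = as.character(cancer_id),
         gene_ids = as.character(gene_ids),
         X = X, y = time, delta = status,
         n = n, p = ncol(X), canonical = FALSE),
    class = "cancer_dataset"
  )
}

#' @export
print.cancer_dataset <- function(x, ...) {
  cat(sprintf("<cancer_dataset %s: n = %d, p = %d, events = %d%s>\n",
              x$cancer_id, x$n, x$p, sum(x$delta),
              if (x$canonical) ", canonical (log scale, sorted)" else ""))
  invisible(x)
}

#' Load one cohort from cBioPortal-style text exports
#'
#' Joins a tab-separated expression table with a tab-separated clinical
#' table on sample identifiers, keeping only samples present in both, and
#' returns a raw (not yet canonicalized) [cancer_dataset()].
#'
#' The expression dialect is auto-detected from the header: a first column
#' named like a gene symbol column (`Hugo_Symbol`, `gene`, ...) means a
#' genes x samples matrix (the cBioPortal RNA-seq V2 export); otherwise the
#' table is read as samples x genes with sample IDs in the first column.
#'
#' @param expression_table path to the expression TSV.
#' @param clinical_table path to the clinical TSV.
#' @param cancer_id cohort label.
#' @param orientation `"auto"` (default), `"genes_by_samples"`, or
#'   `"samples_by_genes"`.
#' @param sample_col,time_col,status_col clinical column names (defaults
#'   `"SAMPLE_ID"`, `"OS_MONTHS"`, `"OS_STATUS"`).
#' @param death_values,alive_values character vectors of status strings
#'   mapped to 1 and 0 respectively (case-insensitive). Numeric 0/1 status
#'   passes through unchanged.
#' @return A raw `cancer_dataset` (times in months).
#' @export
load_cancer_dataset <- function(expression_table, clinical_table,
                                cancer_id = "cohort",
                                orientation = c("auto", "genes_by_samples",
                                                "samples_by_genes"),
                                sample_col = "SAMPLE_ID",
                                time_col = "OS_MONTHS",
                                status_col = "OS_STATUS",
                                death_values = c("DECEASED", "1:DECEASED",
                                                 "DEAD", "1"),
                                alive_values = c("LIVING", "0:LIVING",
                                                 "ALIVE", "CENSORED", "0")) {
  orientation <- match.arg(orientation)
  expr <- utils::read.delim(expression_table, check.names = FALSE,
                            stringsAsFactors = FALSE)
  clin <- utils::read.delim(clinical_table, check.names = FALSE,
                            stringsAsFactors = FALSE)
  for (col in c(sample_col, time_col, status_col)) {
    if (!col %in% names(clin)) {
      stop("clinical table is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  if (ncol(expr) < 2) stop("expression table needs id column plus data",
                           call. = FALSE)
  gene_like <- c("hugo_symbol", "gene", "gene_symbol", "gene_id", "symbol")
  first <- tolower(names(expr)[1])
  if (orientation == "auto") {
    orientation <- if (first %in% gene_like) "genes_by_samples"
                   else "samples_by_genes"
  }
  if (orientation == "genes_by_samples") {
    genes <- as.character(expr[[1]])
    M <- t(as.matrix(expr[, -1, drop = FALSE]))   # samples x genes
    colnames(M) <- genes
    sample_ids <- names(expr)[-1]
  } else {
    sample_ids <- as.character(expr[[1]])
    M <- as.matrix(expr[, -1, drop = FALSE])
    genes <- names(expr)[-1]
    colnames(M) <- genes
  }
  storage.mode(M) <- "double"
  rownames(M) <- sample_ids

  clin_ids <- as.character(clin[[sample_col]])
  shared <- intersect(sample_ids, clin_ids)
  if (length(shared) == 0) {
    stop("no overlapping samples between expression and clinical tables",
         call. = FALSE)
  }
  clin <- clin[match(shared, clin_ids), , drop = FALSE]
  M <- M[shared, , drop = FALSE]

  time <- as.numeric(clin[[time_col]])
  raw_status <- clin[[status_col]]
  status <- map_status(raw_status, death_values, alive_values)
  bad <- which(!is.na(time) & time <= 0)
  if (length(bad)) {
    stop("nonpositive survival time for sample(s): ",
         paste(shared[bad], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(time) & !is.na(status)
  cancer_dataset(M[keep, , drop = FALSE], time[keep], status[keep],
                 cancer_id = cancer_id, gene_ids = genes)
}

# Map clinical status strings/numbers onto {0, 1}; unrecognized values error.
map_status <- function(status, death_values, alive_values) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1) | is.na(status))) {
      stop("numeric status values must be 0/1", call. = FALSE)
    }
    return(as.numeric(status))
  }
  s <- toupper(trimws(as.character(status)))
  out <- rep(NA_real_, length(s))
  out[s %in% toupper(death_values)] <- 1
  out[s %in% toupper(alive_values)] <- 0
  unknown <- unique(s[is.na(out) & !is.na(s) & s != ""])
  if (length(unknown)) {
    stop("unrecognized status value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Canonicalize a cohort: log-transform times and sort
#'
#' Replaces times by their natural logarithm and sorts rows ascending in
#' observed (log) time; at tied times, events (`delta = 1`) precede censored
#' rows — the standard Kaplan-Meier convention. Idempotent.
#'
#' @param dataset a [cancer_dataset()].
#' @return A canonical `cancer_dataset` with `y` on the log scale.
#' @export
canonicalize <- function(dataset) {
  stopifnot(inherits(dataset, "cancer_dataset"))
  y <- dataset$y
  if (!dataset$canonical) {
    if (any(y <= 0)) {
      stop("nonpositive survival time(s) at row(s): ",
           paste(which(y <= 0), collapse = ", "), call. = FALSE)
    }
    y <- log(y)
  }
  ord <- order(y, -dataset$delta)
  dataset$y <- y[ord]
  dataset$delta <- dataset$delta[ord]
  dataset$X <- dataset$X[ord, , drop = FALSE]
  dataset$canonical <- TRUE
  dataset
}

#' Align multiple cohorts on a shared gene set
#'
#' Restricts every cohort to the genes present in all cohorts (and in the
#' optional panel), reindexed identically in lexicographic order so the
#' fusion penalties compare like with like.
#'
#' @param datasets list of two or more [cancer_dataset()] objects.
#' @param panel optional character vector of gene symbols (e.g. a
#'   pan-cancer panel) to intersect with.
#' @return A `multi_cancer_data` object: list with `datasets`, `K`, `p`,
#'   `gene_ids`, `cancer_ids`.
#' @export
align_genes <- function(datasets, panel = NULL) {
  if (length(datasets) < 2) stop("need at least two cohorts", call. = FALSE)
  stopifnot(all(vapply(datasets, inherits, logical(1), "cancer_dataset")))
  shared <- Reduce(intersect, lapply(datasets, `[[`, "gene_ids"))
  if (!is.null(panel)) shared <- intersect(shared, as.character(panel))
  if (length(shared) == 0) {
    stop("empty gene intersection across cohorts", call. = FALSE)
  }
  shared <- sort(shared, method = "radix")
  datasets <- lapply(datasets, function(d) {
    idx <- match(shared, d$gene_ids)
    d$X <- d$X[, idx, drop = FALSE]
    d$gene_ids <- shared
    d$p <- length(shared)
    d
  })
  multi_cancer_data(datasets)
}

#' Bundle canonical cohorts that already share a gene set
#'
#' @param datasets list of [cancer_dataset()] with identical `gene_ids`.
#' @return A `multi_cancer_data` object.
#' @export
multi_cancer_data <- function(datasets) {
  if (length(datasets) < 2) stop("need at least two cohorts", call. = FALSE)
  ref <- datasets[[1]]$gene_ids
  same <- vapply(datasets, function(d) identical(d$gene_ids, ref), logical(1))
  if (!all(same)) {
    stop("cohorts do not share an identical ordered gene set; ",
         "run align_genes() first", call. = FALSE)
  }
  structure(
    list(datasets = datasets,
         K = length(datasets),
         p = length(ref),
         gene_ids = ref,
         cancer_ids = vapply(datasets, `[[`, character(1), "cancer_id")),
    class = "multi_cancer_data"
  )
}

#' @export
print.multi_cancer_data <- function(x, ...) {
  cat(sprintf("<multi_cancer_data: K = %d cohorts, p = %d shared genes>\n",
              x$K, x$p))
  for (d in x$datasets) print(d)
  invisible(x)
}

#' Canonicalize every cohort in a multi-cohort bundle
#' @param data a `multi_cancer_data` object.
#' @return The bundle with each cohort canonicalized.
#' @export
canonicalize_all <- function(data) {
  stopifnot(inherits(data, "multi_cancer_data"))
  data$datasets <- lapply(data$datasets, canonicalize)
  data
}

#' Read a gene panel file (one symbol per line)
#' @param path text file with one gene symbol per line.
#' @return Character vector of symbols.
#' @export
read_gene_panel <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' KM-weighted standardization of a cohort
#'
#' Centers `y` and every expression column by their Kaplan-Meier-weighted
#' means, and scales each retained column so that
#' `sum(w * x^2) / n == 1` — the normalization under which the
#' coordinate-descent subproblem has unit curvature. Columns with (near)
#' zero weighted variance are flagged degenerate and excluded from fitting.
#' Intercepts are absorbed by the centering and recovered from the returned
#' record.
#'
#' @param dataset a canonical [cancer_dataset()].
#' @param weights a [km_weights()] object aligned to the dataset rows.
#' @param eps scale threshold below which a column counts as constant.
#' @return List with `Xs` (standardized matrix, degenerate columns zeroed),
#'   `yc` (centered log-times), and `record` — a `standardization_record`
#'   with `y_center`, `x_center`, `x_scale`, `keep`, `n`, `wsum`.
#' @export
weighted_standardize <- function(dataset, weights, eps = 1e-10) {
  stopifnot(inherits(dataset, "cancer_dataset"),
            inherits(weights, "km_weights"))
  w <- weights$w
  if (length(w) != dataset$n) {
    stop("weights are not aligned to the dataset rows", call. = FALSE)
  }
  wsum <- sum(w)
  if (wsum <= 0) stop("degenerate weights: all Kaplan-Meier weights are zero",
                      call. = FALSE)
  n <- dataset$n
  y_center <- sum(w * dataset$y) / wsum
  x_center <- stats::setNames(as.numeric(crossprod(dataset$X, w)) / wsum,
                              dataset$gene_ids)
  Xc <- sweep(dataset$X, 2, x_center, "-")
  msq <- stats::setNames(as.numeric(crossprod(Xc^2, w)) / n,
                         dataset$gene_ids)
  keep <- msq > eps
  x_scale <- ifelse(keep, sqrt(msq), 1)
  Xs <- sweep(Xc, 2, x_scale, "/")
  if (any(!keep)) Xs[, !keep] <- 0
  record <- structure(
    list(y_center = y_center, x_center = x_center, x_scale = x_scale,
         keep = keep, n = n, wsum = wsum,
         gene_ids = dataset$gene_ids, cancer_id = dataset$cancer_id),
    class = "standardization_record"
  )
  list(Xs = Xs, yc = dataset$y - y_center, record = record)
}

# Map standardized-scale slopes back to the original data scale and recover
# the intercept implied by KM-weighted centering.
unstandardize_coef <- function(eta_std, record) {
  eta <- ifelse(record$keep, eta_std / record$x_scale, 0)
  alpha <- record$y_center - sum(eta * record$x_center)
  list(eta = eta, alpha = alpha)
}
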