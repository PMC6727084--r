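#' Kaplan-Meier (Stute) weights for a canonical cohort
#'
#' Computes the jump weights of the Kaplan-Meier estimator of the survival
#' time distribution, used to weight the least-squares AFT loss so censored
#' rows contribute correctly. For data sorted ascending in observed time,
#'
#'   w_1 = delta_1 / n,
#'   w_i = delta_i / (n - i + 1) * prod_{l < i} ((n - l)/(n - l + 1))^delta_l.
#'
#' Censored rows get weight zero; the weights sum to one exactly when the
#' largest observation is an event, and to less than one otherwise (the KM
#' estimator then leaves mass beyond the last observed time).
#'
#' @param dataset a canonical [cancer_dataset()] (sorted ascending in `y`,
#'   events before censorings at ties).
#' @param renormalize if `TRUE`, rescale the weights to sum to one when the
#'   last observation is censored. Default `FALSE` (raw KM jumps).
#' @return A `km_weights` object: list with `w` (length-n weights) and
#'   `cancer_id`.
#' @export
compute_km_weights <- function(dataset, renormalize = FALSE) {
  stopifnot(inherits(dataset, "cancer_dataset"))
  if (!dataset$canonical) {
    stop("dataset must be canonicalized (sorted) before computing KM weights",
         call. = FALSE)
  }
  if (is.unsorted(dataset$y)) {
    stop("dataset rows are not sorted ascending in y", call. = FALSE)
  }
  n <- dataset$n
  delta <- dataset$delta
  # survival factors ((n-l)/(n-l+1))^delta_l, cumulative product up to l = i-1
  l <- seq_len(n)
  fac <- ((n - l) / (n - l + 1))^delta
  cum <- c(1, cumprod(fac)[-n])
  w <- delta / (n - l + 1) * cum
  if (renormalize && sum(w) > 0) w <- w / sum(w)
  structure(list(w = w, cancer_id = dataset$cancer_id), class = "km_weights")
}

#' @export
print.km_weights <- function(x, ...) {
  cat(sprintf("<km_weights %s: n = %d, sum(w) = %.6f>\n",
              x$cancer_id, length(x$w), sum(x$w)))
  invisible(x)
}

#' KM weights for every cohort in a bundle
#' @param data a canonical `multi_cancer_data`.
#' @param renormalize passed to [compute_km_weights()].
#' @return List of `km_weights`, one per cohort.
#' @export
compute_km_weights_all <- function(data, renormalize = FALSE) {
  stopifnot(inherits(data, "multi_cancer_data"))
  lapply(data$datasets, compute_km_weights, renormalize = renormalize)
}
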