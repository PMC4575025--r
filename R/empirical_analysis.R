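# Pairwise forward-in-time growth-rate estimation on measured series,
# the stability filter, and the empirical false-positive rate.

#' All forward-in-time scan pairs of a series
#'
#' Every ordered pair of scans (i < j after date sorting) yields one
#' growth-rate estimate k = ln(Vj/Vi)/(tj - ti); a series with n scans
#' yields n(n-1)/2 pairs. When a decision window is supplied, each pair
#' is also classified (strict inequalities, positive-growth band only).
#'
#' @param series A [nodule_series()] with distinct scan dates.
#' @param window Optional [malignant_window()]; when given, a `positive`
#'   column is filled.
#' @return A data.frame with columns `nodule_id`, `scan_index_1`,
#'   `scan_index_2`, `v1`, `v2`, `delta_t`, `k` (and `positive`).
#' @export
forward_pairs <- function(series, window = NULL) {
  stopifnot(inherits(series, "nodule_series"))
  if (anyDuplicated(series$days)) {
    stop("series ", series$nodule_id,
         " has duplicate scan dates: delta_t = 0 leaves k undefined")
  }
  n <- length(series$volumes)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]
  j <- idx[2, ]
  dt <- series$days[j] - series$days[i]
  out <- data.frame(
    nodule_id = series$nodule_id,
    scan_index_1 = i,
    scan_index_2 = j,
    v1 = series$volumes[i],
    v2 = series$volumes[j],
    delta_t = dt,
    k = log(series$volumes[j] / series$volumes[i]) / dt,
    stringsAsFactors = FALSE
  )
  if (!is.null(window)) {
    out$positive <- out$k > window$k_low & out$k < window$k_high
  }
  out
}

#' Empirical false-positive rate of a stable cohort
#'
#' Classifies every forward-in-time scan pair of every series by the
#' decision window and reports the positive fraction. For a cohort of
#' truly stable nodules every positive call is a false positive driven
#' by measurement noise alone.
#'
#' @param cohort A non-empty list of [nodule_series()] (each >= 2 scans).
#' @param window A [malignant_window()].
#' @return A list: `fraction`, `positives`, `total_pairs`, and `pairs`
#'   (the full per-pair table for scatter reproduction).
#' @export
empirical_fpr <- function(cohort, window = malignant_window()) {
  if (length(cohort) == 0) stop("empty cohort")
  pairs <- do.call(rbind, lapply(cohort, forward_pairs, window = window))
  list(
    fraction = mean(pairs$positive),
    positives = sum(pairs$positive),
    total_pairs = nrow(pairs),
    pairs = pairs
  )
}

#' Stability filter on measured volumes
#'
#' A nodule is accepted as stable when no measurement deviates from the
#' reference volume by more than `threshold` (default 25%). The
#' reference is the per-nodule mean by default (the variance analysis is
#' mean-centered); the first scan is available as an alternative.
#' Scale-invariant: rescaling all volumes leaves the verdict unchanged.
#'
#' @param series A [nodule_series()] or numeric volume vector (>= 2).
#' @param threshold Maximum allowed relative deviation (default 0.25).
#' @param reference `"mean"` or `"first"`.
#' @return `TRUE` if the series passes the filter.
#' @export
stability_filter <- function(series, threshold = 0.25,
                             reference = c("mean", "first")) {
  reference <- match.arg(reference)
  volumes <- if (inherits(series, "nodule_series")) series$volumes else as.numeric(series)
  if (length(volumes) < 2) stop("at least 2 scans required")
  ref <- if (reference == "mean") mean(volumes) else volumes[1]
  max(abs(volumes - ref)) / ref <= threshold
}

#' Empirical FPR under simulated scan intervals
#'
#' For same-day repeat measurement pairs (e.g. "coffee-break" repeat
#' scans), re-dates each pair to each simulated interval, recomputes
#' k = ln(V2/V1)/delta_t, and classifies by the window — mapping out the
#' empirical FPR as a function of the scan interval.
#'
#' @param cohort List of [nodule_series()], each with exactly 2
#'   measurements.
#' @param delta_ts Simulated scan intervals (days), > 0.
#' @param window A [malignant_window()].
#' @return A data.frame with columns `delta_t`, `fpr`, `positives`,
#'   `total`.
#' @export
simulated_interval_sweep <- function(cohort, delta_ts = seq(30, 180, by = 10),
                                     window = malignant_window()) {
  if (length(cohort) == 0) stop("empty cohort")
  n_scans <- vapply(cohort, function(s) length(s$volumes), integer(1))
  if (any(n_scans != 2)) {
    stop("every series must have exactly 2 measurements; found counts: ",
         paste(unique(n_scans), collapse = ", "))
  }
  if (any(delta_ts <= 0)) stop("`delta_ts` must be > 0")
  log_ratio <- vapply(cohort, function(s) log(s$volumes[2] / s$volumes[1]),
                      numeric(1))
  do.call(rbind, lapply(delta_ts, function(dt) {
    k <- log_ratio / dt
    pos <- k > window$k_low & k < window$k_high
    data.frame(delta_t = dt, fpr = mean(pos), positives = sum(pos),
               total = length(pos))
  }))
}
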