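# Per-nodule repeat-measurement statistics and the through-origin
# regression of volume SD on mean volume (the proportional-error slope a).

#' Summarize a nodule's repeat measurements
#'
#' Arithmetic mean, sample SD (n-1 denominator) and coefficient of
#' variation of one nodule's measured volumes. With more than two scans
#' per nodule, Bland-Altman analysis does not apply; per-nodule SD
#' against mean is the repeated-measures analogue.
#'
#' @param series A [nodule_series()] (>= 2 scans), or a bare numeric
#'   vector of volumes.
#' @param nodule_id Identifier used when `series` is a bare vector.
#' @return A one-row data.frame: `nodule_id`, `mean_volume`, `sd_volume`,
#'   `cv`, `n_scans`, `calcified`.
#' @examples
#' summarize_nodule(c(90, 100, 110))  # V = 100, SD = 10, CV = 0.10
#' @export
summarize_nodule <- function(series, nodule_id = "nodule") {
  if (inherits(series, "nodule_series")) {
    volumes <- series$volumes
    nodule_id <- series$nodule_id
    calcified <- series$calcified
  } else {
    volumes <- as.numeric(series)
    calcified <- FALSE
  }
  if (length(volumes) < 2) {
    stop("at least 2 measurements are required to estimate a volume SD")
  }
  if (any(volumes <= 0)) stop("volumes must be > 0")
  m <- mean(volumes)
  s <- stats::sd(volumes)
  data.frame(
    nodule_id = as.character(nodule_id),
    mean_volume = m,
    sd_volume = s,
    cv = s / m,
    n_scans = length(volumes),
    calcified = calcified,
    stringsAsFactors = FALSE
  )
}

#' Summarize every nodule in a cohort
#'
#' @param cohort A list of [nodule_series()] objects.
#' @return A data.frame with one row per nodule (see [summarize_nodule()]).
#' @export
summarize_cohort <- function(cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  do.call(rbind, lapply(cohort, summarize_nodule))
}

#' Fit the proportional volume-error model
#'
#' Least-squares regression of per-nodule volume SD on mean volume with
#' the intercept fixed at zero: \eqn{\sigma_V = a\bar V}. The single
#' slope `a` is the proportional measurement-error coefficient that
#' drives all downstream growth-rate error propagation.
#'
#' Two r-squared conventions are reported. `r_squared` is the centered
#' form \eqn{1 - SS_{res}/\sum(\sigma_V - \bar\sigma_V)^2}, comparable
#' with ordinary regression r-squared; `r_squared_uncentered` is the
#' through-origin form \eqn{1 - SS_{res}/\sum \sigma_V^2} that `lm`
#' reports for a no-intercept fit. The p-value is the two-sided t-test
#' of slope = 0 on n-1 degrees of freedom.
#'
#' @param summaries A data.frame with columns `mean_volume` and
#'   `sd_volume` (from [summarize_cohort()]), or a list of one-row
#'   summaries which will be row-bound.
#' @return An object of class `proportional_error_fit`: `slope`,
#'   `slope_se`, `r_squared`, `r_squared_uncentered`, `p_value`,
#'   `n_nodules`.
#' @examples
#' s <- data.frame(mean_volume = c(100, 1000), sd_volume = c(5.7, 57))
#' fit_proportional_sd(s)$slope  # 0.057 exactly
#' @export
fit_proportional_sd <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, summaries)
  }
  stopifnot(is.data.frame(summaries),
            all(c("mean_volume", "sd_volume") %in% names(summaries)))
  if (nrow(summaries) < 2) {
    stop("at least 2 nodule summaries are required for a slope estimate")
  }
  vbar <- summaries$mean_volume
  sv <- summaries$sd_volume
  if (any(vbar <= 0)) stop("mean volumes must be > 0")
  if (any(sv < 0)) stop("volume SDs must be >= 0")
  fit <- stats::lm(sv ~ 0 + vbar)
  # a noiseless proportional line is a legitimate input (r^2 = 1);
  # drop summary.lm's "essentially perfect fit" warning for that case
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  resid_ss <- sum(stats::residuals(fit)^2)
  tot_centered <- sum((sv - mean(sv))^2)
  structure(
    list(
      slope = unname(co[1, "Estimate"]),
      slope_se = unname(co[1, "Std. Error"]),
      r_squared = if (tot_centered > 0) 1 - resid_ss / tot_centered else 1,
      r_squared_uncentered = sm$r.squared,
      p_value = unname(co[1, "Pr(>|t|)"]),
      n_nodules = nrow(summaries)
    ),
    class = "proportional_error_fit"
  )
}

#' @export
print.proportional_error_fit <- function(x, ...) {
  cat(sprintf("Proportional volume-error fit (sigma_V = a*Vbar), %d nodules\n",
              x$n_nodules))
  cat(sprintf("  a = %.4f +/- %.4f,  r^2 = %.3f (uncentered %.3f),  p = %.3g\n",
              x$slope, x$slope_se, x$r_squared, x$r_squared_uncentered,
              x$p_value))
  invisible(x)
}

#' Fraction of larger nodules with small measurement CV
#'
#' Proportion of nodules above a volume threshold whose coefficient of
#' variation falls below a limit; under proportional error with slope
#' `a`, per-nodule CV concentrates near `a`.
#'
#' @param summaries A data.frame with `mean_volume` and `cv` columns.
#' @param volume_threshold Lower volume bound (mm^3), exclusive.
#' @param cv_limit CV bound, exclusive (default 0.15).
#' @return The fraction in `[0, 1]`; `NaN` if no nodule exceeds the
#'   threshold.
#' @export
cv_profile <- function(summaries, volume_threshold = 100, cv_limit = 0.15) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, summaries)
  }
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    stop("`summaries` must be a non-empty data.frame")
  }
  above <- summaries$mean_volume > volume_threshold
  if (!any(above)) return(NaN)
  mean(summaries$cv[above] < cv_limit)
}
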