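# Analytic misclassification rates for the doubling-time decision band
# and the optimal follow-up scan interval.

#' The malignancy decision window in growth-rate space
#'
#' Doubling times between `dt_min` and `dt_max` days are read as
#' positive for malignancy; in rate space that is the band
#' \eqn{\ln 2/dt_{max} < k < \ln 2/dt_{min}}. The defaults 30 and 400
#' days give 0.00173 < k < 0.0231 day^-1. Membership is strict on both
#' sides, and only positive growth counts: apparent shrinkage is never a
#' positive call.
#'
#' @param dt_min,dt_max Doubling-time limits (days), 0 < dt_min < dt_max.
#' @return An object of class `growth_window`: `k_low`, `k_high`,
#'   `dt_min`, `dt_max`.
#' @export
malignant_window <- function(dt_min = 30, dt_max = 400) {
  if (!is.finite(dt_min) || !is.finite(dt_max) || dt_min <= 0 || dt_max <= dt_min) {
    stop("need 0 < dt_min < dt_max")
  }
  structure(
    list(k_low = log(2) / dt_max, k_high = log(2) / dt_min,
         dt_min = dt_min, dt_max = dt_max),
    class = "growth_window"
  )
}

#' @export
print.growth_window <- function(x, ...) {
  cat(sprintf("Decision window: DT %g-%g days  <=>  %.5f < k < %.5f /day\n",
              x$dt_min, x$dt_max, x$k_low, x$k_high))
  invisible(x)
}

#' Lognormal model of the malignant growth-rate distribution
#'
#' Growth rates of malignant nodules measured at long scan intervals are
#' well described by a lognormal law in `k`; the reference fit has
#' log-mean ln(0.015) and log-SD 0.83. The `amplitude` is a scale
#' factor carried by histogram fits to raw counts (1 means a normalized
#' density); probability computations always use the normalized density.
#'
#' @param mu_log Mean of ln k.
#' @param sigma_log SD of ln k, > 0.
#' @param amplitude Positive scale factor for count-scale curves.
#' @return An object of class `lognormal_growth_model`.
#' @export
lognormal_growth_model <- function(mu_log = log(0.015), sigma_log = 0.83,
                                   amplitude = 1) {
  if (!is.finite(sigma_log) || sigma_log <= 0) stop("`sigma_log` must be > 0")
  if (!is.finite(amplitude) || amplitude <= 0) stop("`amplitude` must be > 0")
  structure(
    list(mu_log = mu_log, sigma_log = sigma_log, amplitude = amplitude),
    class = "lognormal_growth_model"
  )
}

#' @export
print.lognormal_growth_model <- function(x, ...) {
  cat(sprintf(
    "Lognormal growth-rate model: mu_L = %.4f (median k = %.4g /day), sigma_L = %.3f, amplitude = %.4g\n",
    x$mu_log, exp(x$mu_log), x$sigma_log, x$amplitude))
  invisible(x)
}

#' Analytic false-positive rate for stable nodules
#'
#' A truly stable nodule has k = 0; measurement noise alone spreads its
#' estimated k as a zero-mean normal with SD
#' \eqn{\sigma_k = a\sqrt{2}/\Delta t}. The false-positive rate is the
#' normal mass falling inside the malignancy window:
#' \deqn{FPR(\Delta t) = \Phi(k_{high}/\sigma_k) - \Phi(k_{low}/\sigma_k).}
#' Noiseless measurements (`a = 0`) never misclassify.
#'
#' @param delta_t Scan interval (days), > 0. Vectorized.
#' @param a Proportional-error slope, >= 0.
#' @param window A [malignant_window()].
#' @return Probability in `[0, 1]` per `delta_t`.
#' @examples
#' stable_fpr(81, 0.057)  # about 0.041
#' @export
stable_fpr <- function(delta_t, a, window = malignant_window()) {
  if (any(!is.finite(delta_t)) || any(delta_t <= 0)) {
    stop("`delta_t` must be > 0")
  }
  if (length(a) != 1 || !is.finite(a) || a < 0) stop("`a` must be a scalar >= 0")
  if (a == 0) return(rep(0, length(delta_t)))
  sk <- sigma_k_proportional(a, delta_t)
  stats::pnorm(window$k_high / sk) - stats::pnorm(window$k_low / sk)
}

#' True-positive rate without measurement blurring
#'
#' The lognormal probability mass of malignant growth rates inside the
#' decision window — the ceiling the blurred TPR approaches as the scan
#' interval grows.
#'
#' @param model A [lognormal_growth_model()].
#' @param window A [malignant_window()].
#' @return Probability in `[0, 1]`.
#' @examples
#' tpr_pure(lognormal_growth_model())  # about 0.69
#' @export
tpr_pure <- function(model = lognormal_growth_model(),
                     window = malignant_window()) {
  stats::plnorm(window$k_high, model$mu_log, model$sigma_log) -
    stats::plnorm(window$k_low, model$mu_log, model$sigma_log)
}

#' Measurement-blurred malignant growth-rate density
#'
#' The density of the *estimated* k for malignant nodules at scan
#' interval `delta_t`: the true lognormal density convolved with the
#' zero-mean normal measurement kernel of SD \eqn{a\sqrt{2}/\Delta t}.
#'
#' @param k Evaluation points (day^-1); may be negative (blurring pushes
#'   mass below zero).
#' @param model A [lognormal_growth_model()].
#' @param a Proportional-error slope, >= 0.
#' @param delta_t Scan interval (days), > 0.
#' @return Density values at `k` (normalized; `amplitude` is ignored).
#' @export
blurred_density <- function(k, model = lognormal_growth_model(), a = 0.057,
                            delta_t = 81) {
  sk <- sigma_k_proportional(a, delta_t)
  if (sk == 0) return(stats::dlnorm(k, model$mu_log, model$sigma_log))
  # substitute x = exp(u): the lognormal factor becomes a normal density
  # in u; restrict to the kernel's effective support so the adaptive
  # rule cannot step over the narrow Gaussian spike
  lo_ln <- model$mu_log - 15 * model$sigma_log
  hi_ln <- model$mu_log + 15 * model$sigma_log
  vapply(k, function(ki) {
    if (ki + 10 * sk <= 0) return(0)
    lo <- max(lo_ln,
              if (ki - 10 * sk > 0) log(ki - 10 * sk) else lo_ln)
    hi <- min(hi_ln, log(ki + 10 * sk))
    if (hi <= lo) return(0)
    stats::integrate(
      function(u) stats::dnorm(u, model$mu_log, model$sigma_log) *
        stats::dnorm(ki - exp(u), 0, sk),
      lower = lo, upper = hi,
      rel.tol = 1e-8, abs.tol = 1e-12, stop.on.error = TRUE
    )$value
  }, numeric(1))
}

#' True-positive rate with measurement blurring
#'
#' Integral over the decision window of the malignant growth-rate
#' density convolved with the measurement kernel. Evaluated by exchanging
#' the order of integration, which turns the double integral into a
#' single adaptive quadrature:
#' \deqn{TPR(\Delta t) = \int_0^\infty f_{LN}(x)\,
#'   [\Phi((k_{high}-x)/\sigma_k) - \Phi((k_{low}-x)/\sigma_k)]\,dx.}
#' Converges to [tpr_pure()] as `delta_t` grows.
#'
#' @param model A [lognormal_growth_model()].
#' @param a Proportional-error slope, >= 0.
#' @param delta_t Scan interval (days), > 0.
#' @param window A [malignant_window()].
#' @param abs_tol Absolute quadrature tolerance (default 1e-6); failure
#'   to reach it is an error, never a silent approximation.
#' @return Probability in `[0, 1]`.
#' @export
tpr_blurred <- function(model = lognormal_growth_model(), a = 0.057,
                        delta_t = 81, window = malignant_window(),
                        abs_tol = 1e-6) {
  if (length(delta_t) != 1 || !is.finite(delta_t) || delta_t <= 0) {
    stop("`delta_t` must be a scalar > 0")
  }
  if (a < 0) stop("`a` must be >= 0")
  if (a == 0) return(tpr_pure(model, window))
  sk <- sigma_k_proportional(a, delta_t)
  q <- tryCatch(
    stats::integrate(
      function(u) stats::dnorm(u, model$mu_log, model$sigma_log) *
        (stats::pnorm((window$k_high - exp(u)) / sk) -
           stats::pnorm((window$k_low - exp(u)) / sk)),
      lower = model$mu_log - 12 * model$sigma_log,
      upper = model$mu_log + 12 * model$sigma_log,
      abs.tol = abs_tol, rel.tol = 1e-8, stop.on.error = TRUE
    ),
    error = function(e) stop("blurred-TPR quadrature failed to converge: ",
                             conditionMessage(e))
  )
  if (q$abs.error > abs_tol) {
    stop(sprintf("blurred-TPR quadrature error %.2g exceeds tolerance %.2g",
                 q$abs.error, abs_tol))
  }
  min(max(q$value, 0), 1)
}

#' Shortest scan interval meeting a target false-positive rate
#'
#' Exhaustive scan over integer scan intervals from 1 day upward for the
#' smallest interval whose analytic FPR falls strictly below `alpha`.
#' Because \eqn{\sigma_k = a\sqrt{2}/\Delta t} shrinks with the interval,
#' the FPR eventually decreases monotonically and the first crossing is
#' the optimum.
#'
#' @param a Proportional-error slope, > 0.
#' @param alpha Target FPR in (0, 1) (default 0.05).
#' @param window A [malignant_window()].
#' @param max_days Search bound (default 10000); exceeding it is an error.
#' @return The optimal interval in whole days. A degenerate result of 1
#'   day (target already met at the shortest interval) is returned with
#'   a warning.
#' @examples
#' optimal_interval(0.057, 0.05)  # 77 days
#' @export
optimal_interval <- function(a, alpha = 0.05, window = malignant_window(),
                             max_days = 10000) {
  if (!is.finite(a) || a <= 0) stop("`a` must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)")
  }
  dts <- seq_len(max_days)
  ok <- stable_fpr(dts, a, window) < alpha
  if (!any(ok)) stop("no interval up to ", max_days, " days meets FPR < ", alpha)
  opt <- dts[which(ok)[1]]
  if (opt == 1) {
    warning("target FPR already met at a 1-day interval (degenerate)")
  }
  opt
}

#' Fit a lognormal curve to a growth-rate histogram
#'
#' Least-squares fit of `amplitude * dlnorm(k, mu_log, sigma_log)` to
#' histogram counts at the given bin centers (Levenberg-Marquardt via
#' \pkg{minpack.lm}). The amplitude is estimated and reported, never
#' silently normalized away, because raw-count histograms are not
#' densities.
#'
#' @param bin_centers Bin-center k values (day^-1), > 0, length >= 3.
#' @param counts Non-negative counts, same length.
#' @return A [lognormal_growth_model()] with fitted `mu_log`,
#'   `sigma_log`, `amplitude`.
#' @export
fit_lognormal_to_histogram <- function(bin_centers, counts) {
  bin_centers <- as.numeric(bin_centers)
  counts <- as.numeric(counts)
  if (length(bin_centers) != length(counts)) {
    stop("`bin_centers` and `counts` must have equal length")
  }
  if (length(bin_centers) < 3) stop("at least 3 histogram bins are required")
  if (any(bin_centers <= 0)) stop("bin centers must be > 0 (k is positive)")
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with positive total")
  }
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: need at least 2 nonzero bins")
  }
  # moment-based starting values on the log scale, count-weighted
  w <- counts / sum(counts)
  lx <- log(bin_centers)
  mu0 <- sum(w * lx)
  s0 <- sqrt(max(sum(w * (lx - mu0)^2), 1e-4))
  bw <- if (length(bin_centers) > 1) stats::median(diff(sort(bin_centers))) else 1
  amp0 <- max(sum(counts) * bw, max(counts) / stats::dlnorm(exp(mu0), mu0, s0))
  df <- data.frame(x = bin_centers, y = counts)
  fit <- minpack.lm::nlsLM(
    y ~ amp * stats::dlnorm(x, mu, sig),
    data = df,
    start = list(amp = amp0, mu = mu0, sig = s0),
    lower = c(amp = 1e-12, mu = -Inf, sig = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- stats::coef(fit)
  lognormal_growth_model(mu_log = unname(p["mu"]),
                         sigma_log = unname(p["sig"]),
                         amplitude = unname(p["amp"]))
}

#' FPR/TPR curve over a grid of scan intervals
#'
#' @param a Proportional-error slope, >= 0.
#' @param model A [lognormal_growth_model()].
#' @param window A [malignant_window()].
#' @param delta_ts Scan intervals (days), non-empty, all > 0.
#' @return A data.frame with columns `delta_t`, `fpr`, `tpr`.
#' @export
rate_curve <- function(a, model = lognormal_growth_model(),
                       window = malignant_window(),
                       delta_ts = seq(30, 180, by = 10)) {
  if (length(delta_ts) == 0 || any(delta_ts <= 0)) {
    stop("`delta_ts` must be non-empty and positive")
  }
  data.frame(
    delta_t = delta_ts,
    fpr = stable_fpr(delta_ts, a, window),
    tpr = vapply(delta_ts, function(dt) tpr_blurred(model, a, dt, window),
                 numeric(1))
  )
}
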