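# Exponential growth kinetics and error propagation.
#
# All rate constants are in day^-1, volumes in mm^3, times in days;
# logarithms are natural throughout.

#' Exponential nodule growth model
#'
#' Volume at time `t` under simple exponential growth,
#' \eqn{V(t) = V_0 e^{kt}}. Stable nodules have \eqn{k = 0}; the
#' doubling time is \eqn{DT = \ln 2 / k}.
#'
#' @param v0 Initial volume (mm^3), strictly positive.
#' @param k Exponential growth-rate constant (day^-1). May be negative
#'   (shrinking nodule) or zero (stable).
#' @param t Elapsed time (days).
#' @return Volume at time `t` (mm^3), strictly positive. Vectorized over
#'   any argument.
#' @examples
#' volume_at(100, 0, 365)          # stable: 100
#' volume_at(100, log(2) / 100, 100)  # one doubling: 200
#' @export
volume_at <- function(v0, k, t) {
  if (any(!is.finite(v0)) || any(v0 <= 0)) {
    stop("`v0` must be a finite, strictly positive volume (mm^3)")
  }
  v0 * exp(k * t)
}

#' Construct a volume pair
#'
#' Two volume measurements of the same nodule separated by a known scan
#' interval — the atomic input for growth-rate estimation.
#'
#' @param v1,v2 Volumes at the first and second scan (mm^3), > 0.
#' @param delta_t Elapsed time between scans (days), > 0.
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(v1, v2, delta_t) {
  stopifnot(length(v1) == 1, length(v2) == 1, length(delta_t) == 1)
  if (!is.finite(v1) || v1 <= 0) stop("`v1` must be > 0")
  if (!is.finite(v2) || v2 <= 0) stop("`v2` must be > 0")
  if (!is.finite(delta_t) || delta_t <= 0) {
    stop("`delta_t` must be > 0: growth rate is undefined for a zero scan interval")
  }
  structure(list(v1 = v1, v2 = v2, delta_t = delta_t), class = "volume_pair")
}

#' Growth-rate estimate container
#'
#' Holds the growth-rate constant `k`, its standard error `sigma_k`
#' (NA when not estimated), and the doubling time `DT = ln2/k`
#' (`Inf` for a stable nodule with `k = 0`, negative for shrinkage).
#'
#' @param k Growth-rate constant (day^-1).
#' @param sigma_k Standard error of `k` (day^-1), >= 0, or `NA`.
#' @return An object of class `growth_estimate`.
#' @export
growth_estimate <- function(k, sigma_k = NA_real_) {
  stopifnot(length(k) == 1, is.finite(k))
  if (!is.na(sigma_k) && sigma_k < 0) stop("`sigma_k` must be >= 0")
  structure(
    list(
      k = k,
      sigma_k = sigma_k,
      doubling_time = if (k == 0) Inf else log(2) / k
    ),
    class = "growth_estimate"
  )
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Growth estimate: k = %.6g /day", x$k))
  if (!is.na(x$sigma_k)) cat(sprintf(" (SE %.4g)", x$sigma_k))
  cat(sprintf(", doubling time = %.4g days\n", x$doubling_time))
  invisible(x)
}

#' Growth-rate constant from a scan pair
#'
#' Inverts the exponential growth model for two measurements:
#' \eqn{k = \ln(V_2/V_1) / \Delta t}. Antisymmetric in the two volumes.
#'
#' @param pair A [volume_pair()], or the first volume if `v2` and
#'   `delta_t` are supplied directly.
#' @param v2,delta_t Optional direct arguments (see `pair`).
#' @return A [growth_estimate()] with `sigma_k` unset.
#' @examples
#' k_from_pair(volume_pair(100, 200, 100))$k  # ln2/100
#' @export
k_from_pair <- function(pair, v2 = NULL, delta_t = NULL) {
  if (!inherits(pair, "volume_pair")) {
    pair <- volume_pair(pair, v2, delta_t)
  }
  growth_estimate(log(pair$v2 / pair$v1) / pair$delta_t)
}

#' Convert between doubling time and growth-rate constant
#'
#' `k_from_dt()` and `dt_from_k()` are the mutually inverse maps
#' \eqn{k = \ln 2 / DT} and \eqn{DT = \ln 2 / k}.
#'
#' @param dt Doubling time (days), > 0.
#' @param k Growth-rate constant (day^-1), > 0.
#' @return The corresponding rate constant (day^-1) or doubling time
#'   (days). Vectorized.
#' @examples
#' k_from_dt(c(400, 30))  # the 30-400 day malignancy band in k-space
#' @export
k_from_dt <- function(dt) {
  if (any(!is.finite(dt)) || any(dt <= 0)) stop("doubling time must be > 0")
  log(2) / dt
}

#' @rdname k_from_dt
#' @export
dt_from_k <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("`k` must be > 0")
  log(2) / k
}

#' Propagate volume measurement error into the growth rate
#'
#' First-order error propagation of independent volume errors through
#' \eqn{k = \ln(V_2/V_1)/\Delta t}:
#' \deqn{\sigma_k = \sqrt{\left(\frac{\sigma_{V_1}}{\Delta t\,V_1}\right)^2 +
#'   \left(\frac{\sigma_{V_2}}{\Delta t\,V_2}\right)^2}.}
#'
#' @param v1,v2 Measured volumes (mm^3), > 0.
#' @param sigma_v1,sigma_v2 Measurement SDs of the two volumes (mm^3), >= 0.
#' @param delta_t Scan interval (days), > 0.
#' @return Standard error of `k` (day^-1).
#' @seealso [sigma_k_proportional()] for the closed form under
#'   proportional error.
#' @export
propagate_sigma_k <- function(v1, sigma_v1, v2, sigma_v2, delta_t) {
  if (any(v1 <= 0) || any(v2 <= 0)) stop("volumes must be > 0")
  if (any(sigma_v1 < 0) || any(sigma_v2 < 0)) stop("volume SDs must be >= 0")
  if (any(!is.finite(delta_t)) || any(delta_t <= 0)) {
    stop("`delta_t` must be > 0")
  }
  sqrt((sigma_v1 / (delta_t * v1))^2 + (sigma_v2 / (delta_t * v2))^2)
}

#' Growth-rate standard error under proportional volume error
#'
#' When the volume SD is proportional to the volume, \eqn{\sigma_V = aV},
#' error propagation collapses to
#' \deqn{\sigma_k = a\sqrt{2} / \Delta t,}
#' independent of the nodule volume. This volume independence is what
#' makes a single optimal follow-up interval possible for all nodule
#' sizes.
#'
#' @param a Proportional-error slope (dimensionless), >= 0.
#' @param delta_t Scan interval (days), > 0.
#' @return Standard error of `k` (day^-1). Vectorized.
#' @examples
#' sigma_k_proportional(0.057, 81)
#' @export
sigma_k_proportional <- function(a, delta_t) {
  if (any(a < 0)) stop("`a` must be >= 0")
  if (any(!is.finite(delta_t)) || any(delta_t <= 0)) {
    stop("`delta_t` must be > 0")
  }
  a * sqrt(2) / delta_t
}
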