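# The pipeline's atomic record: one nodule's dated volume measurements.

#' Construct a nodule measurement series
#'
#' One nodule's repeat vCT volume measurements, sorted by scan date.
#' Time enters every downstream computation only through whole-day
#' differences between scan dates.
#'
#' @param nodule_id Identifier (coerced to character).
#' @param dates Scan dates: a `Date` vector, or a numeric vector of day
#'   offsets (converted to dates from an arbitrary origin).
#' @param volumes Measured volumes (mm^3), strictly positive, same
#'   length as `dates`.
#' @param patient_id Optional patient identifier.
#' @param calcified Logical flag: densely calcified nodule.
#' @return An object of class `nodule_series` with elements `nodule_id`,
#'   `patient_id`, `dates`, `days` (days since first scan), `volumes`,
#'   `calcified`.
#' @export
nodule_series <- function(nodule_id, dates, volumes, patient_id = NA_character_,
                          calcified = FALSE) {
  if (is.numeric(dates)) dates <- as.Date("2010-01-01") + dates
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable scan date in series ", nodule_id)
  if (length(dates) != length(volumes)) {
    stop("`dates` and `volumes` must have equal length")
  }
  if (length(volumes) < 2) {
    stop("series ", nodule_id, " has fewer than 2 scans: ",
         "repeat measurements are required")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("all volumes must be finite and > 0 in series ", nodule_id)
  }
  ord <- order(dates)
  dates <- dates[ord]
  volumes <- volumes[ord]
  structure(
    list(
      nodule_id = as.character(nodule_id),
      patient_id = as.character(patient_id),
      dates = dates,
      days = as.numeric(dates - dates[1]),
      volumes = as.numeric(volumes),
      calcified = isTRUE(calcified)
    ),
    class = "nodule_series"
  )
}

#' @export
print.nodule_series <- function(x, ...) {
  cat(sprintf("Nodule series '%s'%s: %d scans over %.0f days, volumes %.1f-%.1f mm^3%s\n",
              x$nodule_id,
              if (is.na(x$patient_id)) "" else paste0(" (patient ", x$patient_id, ")"),
              length(x$volumes), max(x$days),
              min(x$volumes), max(x$volumes),
              if (x$calcified) " [calcified]" else ""))
  invisible(x)
}

#' @export
length.nodule_series <- function(x) length(x$volumes)

#' Coerce a cohort of series to a measurement table
#'
#' @param cohort A list of [nodule_series()] objects.
#' @return A data.frame with columns `patient_id`, `nodule_id`,
#'   `scan_date`, `volume_mm3`, `calcified` — the on-disk measurement
#'   layout used by [read_measurements()] and [write_measurements()].
#' @export
cohort_table <- function(cohort) {
  stopifnot(length(cohort) > 0)
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(
      patient_id = s$patient_id,
      nodule_id = s$nodule_id,
      scan_date = format(s$dates, "%Y-%m-%d"),
      volume_mm3 = s$volumes,
      calcified = s$calcified,
      stringsAsFactors = FALSE
    )
  }))
}
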