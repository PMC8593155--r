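#' Floor respiratory values at their physiological minima
#'
#' FiO2 values below the floor (default 0.30) are set to the floor, PEEP
#' values below 5 cmH2O to 5. Negative values are physically impossible and
#' come back `NA` with a warning; callers drop them.
#'
#' @param variable `"fio2"` or `"peep"`.
#' @param value Numeric vector of measured values.
#' @param config A [surveillance_config()] supplying the floors.
#' @return Numeric vector of floored values (idempotent).
#' @export
floor_respiratory <- function(variable, value,
                              config = surveillance_config()) {
  variable <- match.arg(variable, c("fio2", "peep"))
  floor_at <- if (variable == "fio2") config$fio2_floor else config$peep_floor
  neg <- !is.na(value) & value < 0
  if (any(neg)) {
    warning(sprintf("%d negative %s value(s) dropped", sum(neg), variable),
            call. = FALSE)
    value[neg] <- NA_real_
  }
  pmax(value, floor_at)
}

#' Filter temperatures to the plausible physiological range
#'
#' Values strictly below 35 or strictly above 42 degrees C are excluded as
#' measurement artefacts; the bounds themselves are kept.
#'
#' @param value Numeric vector of temperatures (degrees C).
#' @param config A [surveillance_config()] supplying the bounds.
#' @return Logical vector, `TRUE` where the value is kept.
#' @export
filter_temperature <- function(value, config = surveillance_config()) {
  !is.na(value) & value >= config$temp_exclude_below &
    value <= config$temp_exclude_above
}

#' Exclude the lowest fraction of values
#'
#' Removes the `k = floor(p * n)` smallest values of an admission-day series
#' (ties broken arbitrarily among equal values) before the daily minimum is
#' taken, so that sporadic low measurement artefacts do not masquerade as the
#' lowest daily setting. With sparse series (`n < 1/p`) nothing is removed.
#'
#' @param values Nonempty numeric vector.
#' @param p Fraction in `[0, 0.5]` of lowest values to exclude.
#' @return The surviving values, in their original order.
#' @export
exclude_low_outliers <- function(values, p) {
  if (length(values) == 0L) stop("no values to clean", call. = FALSE)
  stopifnot(p >= 0, p <= 0.5)
  k <- floor(p * length(values))
  if (k == 0L) return(values)
  values[-order(values)[seq_len(k)]]
}

#' Effective worsening threshold under signal-noise tolerance
#'
#' Measured FiO2/PEEP oscillate around their set points, so a genuine rise of
#' one threshold can be measured fractionally short. Under the default
#' shrink-threshold interpretation the minimum required increase becomes
#' `threshold * (1 - t)`.
#'
#' @param threshold The CDC worsening threshold (0.20 FiO2 or 3 cmH2O PEEP).
#' @param t Tolerance fraction in `[0, 0.5]`.
#' @return The effective minimum required increase.
#' @export
effective_threshold <- function(threshold, t) {
  stopifnot(t >= 0, t <= 0.5)
  threshold * (1 - t)
}

new_cleaning_report <- function() {
  c(floored_fio2_count = 0L, floored_peep_count = 0L,
    excluded_temperature_count = 0L, outliers_removed_count = 0L,
    negative_dropped_count = 0L)
}

#' Retrieve the cleaning audit report
#'
#' Per-category counters (floored values, excluded temperatures, removed
#' low outliers, dropped negatives) accumulated while building daily
#' summaries; surveillance audits need this data-quality trail.
#'
#' @param summaries Output of [build_daily_summaries()].
#' @return Named integer vector of counts.
#' @export
cleaning_report <- function(summaries) {
  rep <- attr(summaries, "cleaning_report")
  if (is.null(rep)) rep <- new_cleaning_report()
  rep
}
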