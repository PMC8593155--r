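#' Surveillance configuration
#'
#' Bundles every tunable threshold of the VAE surveillance pipeline. Defaults
#' follow the CDC NHSN VAE protocol plus the data-cleaning settings this
#' package adopts for high-frequency monitor data (5% low-outlier exclusion,
#' 10% worsening-threshold tolerance).
#'
#' @param low_outlier_fraction Fraction `p` of the lowest respiratory values
#'   excluded per admission-day before taking the daily minimum (in
#'   `[0, 0.5]`). Default 0.05.
#' @param tolerance Fraction `t` by which signal-noise tolerance modifies the
#'   worsening thresholds (in `[0, 0.5]`). Default 0.10.
#' @param tolerance_mode How `tolerance` is applied: `"shrink_threshold"`
#'   (default) lowers the required rise to `threshold * (1 - t)`;
#'   `"baseline_allowance"` keeps the full threshold but lets the two baseline
#'   days differ upward by `t * threshold` and still count as stable.
#' @param peep_increase_threshold Daily-minimum PEEP rise (cmH2O) defining
#'   worsening. Default 3.
#' @param fio2_increase_threshold Daily-minimum FiO2 rise (fraction) defining
#'   worsening. Default 0.20.
#' @param fio2_floor,peep_floor Physiological floors: FiO2 below 0.30 is set
#'   to 0.30, PEEP below 5 cmH2O to 5.
#' @param temp_exclude_below,temp_exclude_above Temperatures strictly below
#'   35 or strictly above 42 degrees C are discarded as artefacts.
#' @param fever_above,hypothermia_below Abnormal-temperature bounds for the
#'   IVAC tier: fever when daily max > 38.0, hypothermia when daily
#'   min < 36.0 degrees C.
#' @param wbc_high,wbc_low Abnormal white-cell bounds (10^3 cells/uL):
#'   leukocytosis when daily max >= 12.0, leukopenia when daily min <= 4.0.
#' @param etco2_max_gap_minutes Largest gap between consecutive etCO2
#'   timestamps still counted as continuous ventilation. Default 6.
#' @param noon_window Two clock times (`"HH:MM"` strings or numeric hours)
#'   giving the half-open device-day window around noon. Default
#'   `c("11:00", "13:00")`.
#' @param min_qad Minimum qualifying antimicrobial days for IVAC. Default 4.
#' @param event_washout_days Days after an event onset during which no new
#'   onset may be declared (onset day counts as day 1). Default 14.
#' @param earliest_onset_mv_day First mechanical-ventilation day eligible as
#'   an event onset. Default 3.
#' @param episode_merge_gap_days Ventilation episodes separated by fewer than
#'   this many complete ventilator-free calendar days are merged (default 1:
#'   reintubation the same or next calendar day continues the episode).
#' @param baseline_reference Which baseline day supplies the reference value
#'   the rise is measured from: `"second_day"` (default, the day before
#'   onset, the lower of the two under the stability condition) or
#'   `"first_day"`.
#' @param rng_seed Integer seed recorded for reproducibility of runs that
#'   involve randomness.
#'
#' @return An object of class `vae_config` (a named list).
#' @examples
#' cfg <- surveillance_config(tolerance = 0)
#' cfg$fio2_increase_threshold
#' @export
surveillance_config <- function(low_outlier_fraction = 0.05,
                                tolerance = 0.10,
                                tolerance_mode = c("shrink_threshold",
                                                   "baseline_allowance"),
                                peep_increase_threshold = 3,
                                fio2_increase_threshold = 0.20,
                                fio2_floor = 0.30,
                                peep_floor = 5,
                                temp_exclude_below = 35,
                                temp_exclude_above = 42,
                                fever_above = 38.0,
                                hypothermia_below = 36.0,
                                wbc_high = 12.0,
                                wbc_low = 4.0,
                                etco2_max_gap_minutes = 6,
                                noon_window = c("11:00", "13:00"),
                                min_qad = 4,
                                event_washout_days = 14,
                                earliest_onset_mv_day = 3,
                                episode_merge_gap_days = 1,
                                baseline_reference = c("second_day",
                                                       "first_day"),
                                rng_seed = 1L) {
  tolerance_mode <- match.arg(tolerance_mode)
  baseline_reference <- match.arg(baseline_reference)
  cfg <- list(
    low_outlier_fraction = as.numeric(low_outlier_fraction),
    tolerance = as.numeric(tolerance),
    tolerance_mode = tolerance_mode,
    peep_increase_threshold = as.numeric(peep_increase_threshold),
    fio2_increase_threshold = as.numeric(fio2_increase_threshold),
    fio2_floor = as.numeric(fio2_floor),
    peep_floor = as.numeric(peep_floor),
    temp_exclude_below = as.numeric(temp_exclude_below),
    temp_exclude_above = as.numeric(temp_exclude_above),
    fever_above = as.numeric(fever_above),
    hypothermia_below = as.numeric(hypothermia_below),
    wbc_high = as.numeric(wbc_high),
    wbc_low = as.numeric(wbc_low),
    etco2_max_gap_minutes = as.numeric(etco2_max_gap_minutes),
    noon_window = parse_noon_window(noon_window),
    min_qad = as.integer(min_qad),
    event_washout_days = as.integer(event_washout_days),
    earliest_onset_mv_day = as.integer(earliest_onset_mv_day),
    episode_merge_gap_days = as.integer(episode_merge_gap_days),
    baseline_reference = baseline_reference,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "vae_config"
  validate_config(cfg)
  cfg
}

# noon_window is stored internally as fractional hours, half-open [from, to).
parse_noon_window <- function(x) {
  stopifnot(length(x) == 2L)
  to_hours <- function(v) {
    if (is.numeric(v)) return(as.numeric(v))
    parts <- strsplit(as.character(v), ":", fixed = TRUE)[[1]]
    as.numeric(parts[1]) + as.numeric(parts[2]) / 60
  }
  c(to_hours(x[[1]]), to_hours(x[[2]]))
}

validate_config <- function(cfg) {
  frac_in <- function(v, lo, hi) is.numeric(v) && v >= lo && v <= hi
  if (!frac_in(cfg$low_outlier_fraction, 0, 0.5))
    stop("low_outlier_fraction must lie in [0, 0.5]", call. = FALSE)
  if (!frac_in(cfg$tolerance, 0, 0.5))
    stop("tolerance must lie in [0, 0.5]", call. = FALSE)
  pos <- c("peep_increase_threshold", "fio2_increase_threshold",
           "fio2_floor", "peep_floor", "etco2_max_gap_minutes",
           "min_qad", "event_washout_days", "earliest_onset_mv_day")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  }
  if (cfg$noon_window[2] <= cfg$noon_window[1])
    stop("noon_window must have positive length", call. = FALSE)
  if (cfg$temp_exclude_above <= cfg$temp_exclude_below)
    stop("temperature exclusion bounds are inverted", call. = FALSE)
  invisible(cfg)
}

#' Read a surveillance configuration from a YAML file
#'
#' Keys are the argument names of [surveillance_config()]; absent keys fall
#' back to the defaults, unknown keys are an error (so typos in a
#' configuration cannot silently be ignored).
#'
#' @param path Path to a YAML file.
#' @return A `vae_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(surveillance_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(surveillance_config, raw)
}

#' @export
print.vae_config <- function(x, ...) {
  cat("VAE surveillance configuration\n")
  cat(sprintf("  low-outlier exclusion p: %.2f   tolerance t: %.2f (%s)\n",
              x$low_outlier_fraction, x$tolerance, x$tolerance_mode))
  cat(sprintf("  worsening thresholds: PEEP +%g cmH2O, FiO2 +%g\n",
              x$peep_increase_threshold, x$fio2_increase_threshold))
  cat(sprintf("  floors: FiO2 %.2f, PEEP %g; temperature kept in [%g, %g] C\n",
              x$fio2_floor, x$peep_floor,
              x$temp_exclude_below, x$temp_exclude_above))
  cat(sprintf(
    "  IVAC: temp >%g or <%g C, WBC >=%g or <=%g, >=%d qualifying days\n",
    x$fever_above, x$hypothermia_below, x$wbc_high, x$wbc_low, x$min_qad))
  cat(sprintf(
    "  episodes: etCO2 gap <=%g min, merge gap %d d; washout %d d; onset >= MV day %d\n",
    x$etco2_max_gap_minutes, x$episode_merge_gap_days,
    x$event_washout_days, x$earliest_onset_mv_day))
  invisible(x)
}

as_config <- function(config) {
  if (inherits(config, "vae_config")) return(config)
  if (is.null(config)) return(surveillance_config())
  if (is.character(config) && length(config) == 1L) return(read_config(config))
  if (is.list(config)) return(do.call(surveillance_config, config))
  stop("'config' must be a vae_config, a YAML path, or a named list",
       call. = FALSE)
}
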