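# Tier I/II VAE detection on daily summaries.
#
# Terminology: onset day d is the first day of worsening. The two days
# before (d-2, d-1) are the baseline period; the rise must be sustained on
# d and d+1. All indexing below relies on build_daily_summaries() emitting
# gap-free, date-ordered rows per admission, so row arithmetic equals day
# arithmetic.

# Decimal thresholds (0.20 FiO2) are not exactly representable in binary;
# comparisons carry a 1e-9 slack so an exact decimal rise qualifies.
FP_EPS <- 1e-9

criterion_threshold <- function(criterion, config) {
  if (criterion == "peep") config$peep_increase_threshold
  else config$fio2_increase_threshold
}

criterion_column <- function(criterion) paste0("min_", criterion)

#' Baseline stability check
#'
#' The two calendar days before a candidate onset must be ventilated, have
#' the criterion's daily minimum available, and show a stable or decreasing
#' value (day d-1 at most day d-2, plus the configured allowance under
#' `tolerance_mode = "baseline_allowance"`). Missing data cannot establish
#' stability.
#'
#' @param summaries Gap-free daily summaries of one admission.
#' @param i Row index of the candidate onset day.
#' @param criterion `"peep"` or `"fio2"`.
#' @param config A [surveillance_config()].
#' @return `TRUE`/`FALSE`.
#' @export
baseline_ok <- function(summaries, i, criterion,
                        config = surveillance_config()) {
  if (i < 3L) return(FALSE)
  col <- criterion_column(criterion)
  v1 <- summaries[[col]][i - 2L]  # first baseline day (d-2)
  v2 <- summaries[[col]][i - 1L]  # second baseline day (d-1)
  if (!summaries$ventilated[i - 2L] || !summaries$ventilated[i - 1L])
    return(FALSE)
  if (is.na(v1) || is.na(v2)) return(FALSE)
  allowance <- if (config$tolerance_mode == "baseline_allowance")
    config$tolerance * criterion_threshold(criterion, config) else 0
  v2 <= v1 + allowance + FP_EPS
}

#' Sustained worsening check
#'
#' True when the daily minimum on the onset day and the following day both
#' exceed the baseline reference by at least the effective threshold. The
#' reference is the second baseline day's minimum (day d-1; under the
#' stability condition the lower of the two, hence the conservative choice),
#' or day d-2 with `baseline_reference = "first_day"`.
#'
#' @inheritParams baseline_ok
#' @return `TRUE`/`FALSE`.
#' @export
worsening_ok <- function(summaries, i, criterion,
                         config = surveillance_config()) {
  n <- nrow(summaries)
  if (i < 3L || i + 1L > n) return(FALSE)
  col <- criterion_column(criterion)
  ref_i <- if (config$baseline_reference == "first_day") i - 2L else i - 1L
  ref <- summaries[[col]][ref_i]
  v0 <- summaries[[col]][i]
  v1 <- summaries[[col]][i + 1L]
  if (is.na(ref) || is.na(v0) || is.na(v1)) return(FALSE)
  if (!summaries$ventilated[i] || !summaries$ventilated[i + 1L]) return(FALSE)
  tau <- if (config$tolerance_mode == "shrink_threshold")
    effective_threshold(criterion_threshold(criterion, config),
                        config$tolerance)
  else criterion_threshold(criterion, config)
  (v0 - ref >= tau - FP_EPS) && (v1 - ref >= tau - FP_EPS)
}

#' Detect tier-I ventilator-associated conditions
#'
#' Scans each admission's daily summaries chronologically. A candidate onset
#' day must be at least MV day 3; an event fires when the baseline is stable
#' and the worsening sustained for either criterion (PEEP checked before
#' FiO2; one event per onset day, `criterion` records the first that fired).
#' After an event at onset `o`, no new onset may occur before
#' `o + event_washout_days` (onset day counts as day 1 of the event period).
#'
#' @param summaries Output of [build_daily_summaries()] (one or many
#'   admissions).
#' @param config A [surveillance_config()].
#' @return A data frame of events with columns `admission_id`, `onset_date`,
#'   `tier` (all `"VAC"`), `criterion`, `baseline_value` (the reference the
#'   rise is measured from), `worsening_value` (daily minimum on the onset
#'   day), `mv_day`.
#' @export
detect_vac <- function(summaries, config = surveillance_config()) {
  config <- as_config(config)
  ids <- unique(summaries$admission_id)
  events <- vector("list", length(ids))
  for (a in seq_along(ids)) {
    s <- summaries[summaries$admission_id == ids[a], , drop = FALSE]
    rows <- list()
    next_eligible <- as.Date("0001-01-01")
    for (i in seq_len(nrow(s))) {
      if (is.na(s$mv_day[i]) || s$mv_day[i] < config$earliest_onset_mv_day)
        next
      if (s$date[i] < next_eligible) next
      for (crit in c("peep", "fio2")) {
        if (baseline_ok(s, i, crit, config) &&
            worsening_ok(s, i, crit, config)) {
          col <- criterion_column(crit)
          ref_i <- if (config$baseline_reference == "first_day") i - 2L
          else i - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            admission_id = ids[a], onset_date = s$date[i], tier = "VAC",
            criterion = crit, baseline_value = s[[col]][ref_i],
            worsening_value = s[[col]][i], mv_day = as.integer(s$mv_day[i]),
            stringsAsFactors = FALSE)
          next_eligible <- s$date[i] + config$event_washout_days
          break
        }
      }
    }
    events[[a]] <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  }
  events <- events[!vapply(events, is.null, logical(1))]
  out <- if (length(events) > 0) do.call(rbind, events) else empty_events()
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(admission_id = character(), onset_date = as.Date(character()),
             tier = character(), criterion = character(),
             baseline_value = numeric(), worsening_value = numeric(),
             mv_day = integer(), stringsAsFactors = FALSE)
}

#' Qualifying antimicrobial days of a course
#'
#' Length in calendar days of the contiguous course starting at `start`,
#' where a single-day gap between administered days does not break the
#' course (the gap day counts toward the total); the course ends before the
#' first gap of two or more days.
#'
#' @param dates `Date` vector of days the agent was administered (any
#'   order).
#' @param start The course start date; must be among `dates`.
#' @return Integer number of qualifying days.
#' @export
qualifying_antimicrobial_days <- function(dates, start) {
  dates <- sort(unique(as.Date(dates)))
  start <- as.Date(start)
  if (!start %in% dates) stop("agent not administered on start date",
                              call. = FALSE)
  cur <- start
  for (d in as.list(dates[dates > start])) {
    if (as.integer(d - cur) <= 2L) cur <- d else break
  }
  as.integer(cur - start) + 1L
}

#' Upgrade VACs to tier II (IVAC) where infection criteria are met
#'
#' A VAC with onset `o` becomes an IVAC when, within the five-day window
#' `[o-2, o+2]`: (a) some day shows an abnormal temperature (daily max above
#' the fever bound or daily min below the hypothermia bound) or an abnormal
#' white-cell count (daily max at or above the leukocytosis bound or daily
#' min at or below the leukopenia bound); and (b) some antimicrobial agent is
#' newly started in the window (administered that day but on neither of the
#' two preceding days) and continued for at least `min_qad` qualifying days.
#' The evidence columns record the first satisfied abnormality (scanning
#' days in order; fever, hypothermia, leukocytosis, leukopenia within a day)
#' and the first qualifying agent by start date.
#'
#' @param vac_events Output of [detect_vac()].
#' @param summaries Output of [build_daily_summaries()].
#' @param antimicrobials Data frame from [read_antimicrobials()].
#' @param config A [surveillance_config()].
#' @return The events data frame with `tier` upgraded to `"IVAC"` where
#'   criteria are met and extra columns `ivac_abnormality`, `ivac_agent`,
#'   `ivac_qad` (NA for tier-I events).
#' @export
detect_ivac <- function(vac_events, summaries, antimicrobials,
                        config = surveillance_config()) {
  config <- as_config(config)
  ev <- vac_events
  ev$ivac_abnormality <- rep(NA_character_, nrow(ev))
  ev$ivac_agent <- rep(NA_character_, nrow(ev))
  ev$ivac_qad <- rep(NA_integer_, nrow(ev))
  if (nrow(ev) == 0L) return(ev)
  for (k in seq_len(nrow(ev))) {
    id <- ev$admission_id[k]
    o <- ev$onset_date[k]
    window <- seq(o - 2, o + 2, by = "day")
    s <- summaries[summaries$admission_id == id &
                     summaries$date %in% window, , drop = FALSE]
    s <- s[order(s$date), , drop = FALSE]
    abnormality <- NA_character_
    for (j in seq_len(nrow(s))) {
      if (!is.na(s$max_temp[j]) && s$max_temp[j] > config$fever_above) {
        abnormality <- "fever"
      } else if (!is.na(s$min_temp[j]) &&
                 s$min_temp[j] < config$hypothermia_below) {
        abnormality <- "hypothermia"
      } else if (!is.na(s$max_wbc[j]) && s$max_wbc[j] >= config$wbc_high) {
        abnormality <- "leukocytosis"
      } else if (!is.na(s$min_wbc[j]) && s$min_wbc[j] <= config$wbc_low) {
        abnormality <- "leukopenia"
      }
      if (!is.na(abnormality)) break
    }
    if (is.na(abnormality)) next

    ab <- antimicrobials[antimicrobials$admission_id == id, , drop = FALSE]
    if (nrow(ab) == 0L) next
    given <- paste(ab$agent, ab$date)
    is_start <- ab$date %in% window &
      !(paste(ab$agent, ab$date - 1) %in% given) &
      !(paste(ab$agent, ab$date - 2) %in% given)
    starts <- ab[is_start, , drop = FALSE]
    starts <- starts[order(starts$date, starts$agent), , drop = FALSE]
    for (j in seq_len(nrow(starts))) {
      qad <- qualifying_antimicrobial_days(
        ab$date[ab$agent == starts$agent[j]], starts$date[j])
      if (qad >= config$min_qad) {
        ev$tier[k] <- "IVAC"
        ev$ivac_abnormality[k] <- abnormality
        ev$ivac_agent[k] <- starts$agent[j]
        ev$ivac_qad[k] <- qad
        break
      }
    }
  }
  ev
}

#' Run the full tier I + II detection
#'
#' Convenience wrapper: [detect_vac()] then [detect_ivac()].
#'
#' @inheritParams detect_ivac
#' @param summaries Output of [build_daily_summaries()].
#' @return An events data frame (see [detect_ivac()]).
#' @export
detect_vae <- function(summaries, antimicrobials,
                       config = surveillance_config()) {
  config <- as_config(config)
  detect_ivac(detect_vac(summaries, config), summaries, antimicrobials,
              config)
}
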