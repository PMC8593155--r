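#' Cleaned daily minimum of a respiratory variable
#'
#' Applies the percentile low-outlier exclusion to one admission-day series
#' and then the physiological floor, returning the minimum of what survives.
#' Equivalently, the `(floor(p*n)+1)`-th smallest raw value, floored.
#'
#' @param values Numeric vector of in-episode measurements of one variable on
#'   one admission-day (may be empty).
#' @param variable `"fio2"` or `"peep"`.
#' @param config A [surveillance_config()].
#' @return The daily minimum, or `NA` when no measurement exists.
#' @export
daily_min_respiratory <- function(values, variable,
                                  config = surveillance_config()) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  kept <- exclude_low_outliers(values, config$low_outlier_fraction)
  min(floor_respiratory(variable, kept, config))
}

#' Daily extremes of temperature or white-cell count
#'
#' @param values Numeric vector of one admission-day's measurements, already
#'   range-filtered for temperature; all concurrent sources pooled.
#' @return `c(min, max)`, or `c(NA, NA)` when nothing survives.
#' @export
daily_extremes <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(c(NA_real_, NA_real_))
  range(values)
}

# Daily minima for one admission's in-episode fio2 or peep measurements.
# Returns named numeric vector keyed by date string, plus audit counts.
daily_min_by_date <- function(timestamps, values, variable, config, report) {
  neg <- values < 0
  if (any(neg)) {
    report["negative_dropped_count"] <- report["negative_dropped_count"] +
      sum(neg)
    timestamps <- timestamps[!neg]
    values <- values[!neg]
  }
  if (length(values) == 0L)
    return(list(mins = stats::setNames(numeric(0), character(0)),
                report = report))
  day <- format(calendar_date(timestamps), "%Y-%m-%d")
  floor_at <- if (variable == "fio2") config$fio2_floor else config$peep_floor
  p <- config$low_outlier_fraction
  groups <- split(values, day)
  mins <- vapply(groups, function(v) {
    k <- floor(p * length(v))
    kept_min <- sort(v, partial = k + 1L)[k + 1L]
    max(kept_min, floor_at)
  }, numeric(1))
  report["outliers_removed_count"] <- report["outliers_removed_count"] +
    sum(vapply(groups, function(v) floor(p * length(v)), numeric(1)))
  nfloor <- sum(vapply(groups, function(v) {
    k <- floor(p * length(v))
    sv <- sort(v)
    sum(sv[(k + 1L):length(sv)] < floor_at)
  }, numeric(1)))
  key <- paste0("floored_", variable, "_count")
  report[key] <- report[key] + nfloor
  list(mins = mins, report = report)
}

#' Collapse measurements to one summary row per admission-day
#'
#' Produces the input table of the CDC VAE algorithm: for every calendar day
#' from an admission's first to last measurement day, the cleaned daily
#' minimum FiO2 and PEEP (in-episode measurements only, low-outlier excluded,
#' floored), daily temperature and WBC extremes (all sources pooled,
#' temperature range-filtered), the ventilation flag and MV day number, and
#' the antimicrobial agents newly started that day (administered that day but
#' on neither of the two preceding days).
#'
#' @param measurements Data frame from [read_measurements()] (or the
#'   synthetic generator).
#' @param episodes Data frame from [derive_all_episodes] /
#'   [derive_episodes()] + [merge_adjacent_episodes()], with `admission_id`.
#' @param antimicrobials Data frame from [read_antimicrobials()].
#' @param config A [surveillance_config()].
#' @return A data frame of daily summaries, gap-free and date-ordered within
#'   admission, with a `"cleaning_report"` attribute (see
#'   [cleaning_report()]).
#' @export
build_daily_summaries <- function(measurements, episodes, antimicrobials,
                                  config = surveillance_config()) {
  config <- as_config(config)
  report <- new_cleaning_report()
  ids <- unique(measurements$admission_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    m <- measurements[measurements$admission_id == id, , drop = FALSE]
    ep <- episodes[episodes$admission_id == id, , drop = FALSE]
    ab <- antimicrobials[antimicrobials$admission_id == id, , drop = FALSE]
    res <- summarize_admission(id, m, ep, ab, config, report)
    out[[i]] <- res$summaries
    report <- res$report
  }
  summaries <- do.call(rbind, out)
  if (is.null(summaries)) summaries <- empty_summaries()
  rownames(summaries) <- NULL
  attr(summaries, "cleaning_report") <- report
  summaries
}

empty_summaries <- function() {
  data.frame(admission_id = character(), date = as.Date(character()),
             mv_day = integer(), ventilated = logical(),
             min_fio2 = numeric(), min_peep = numeric(),
             min_temp = numeric(), max_temp = numeric(),
             min_wbc = numeric(), max_wbc = numeric(),
             new_agents = character(), stringsAsFactors = FALSE)
}

summarize_admission <- function(id, m, ep, ab, config, report) {
  dates <- seq(min(calendar_date(m$timestamp)),
               max(calendar_date(m$timestamp)), by = "day")
  n <- length(dates)
  keys <- format(dates, "%Y-%m-%d")
  sm <- data.frame(admission_id = rep(id, n), date = dates,
                   mv_day = rep(NA_integer_, n), ventilated = rep(FALSE, n),
                   min_fio2 = rep(NA_real_, n), min_peep = rep(NA_real_, n),
                   min_temp = rep(NA_real_, n), max_temp = rep(NA_real_, n),
                   min_wbc = rep(NA_real_, n), max_wbc = rep(NA_real_, n),
                   new_agents = rep("", n), stringsAsFactors = FALSE)

  # ventilation flag and MV day from episode calendar spans
  for (j in seq_len(nrow(ep))) {
    span <- dates >= calendar_date(ep$start[j]) &
      dates <= calendar_date(ep$end[j])
    sm$ventilated[span] <- TRUE
    sm$mv_day[span] <- 1L + as.integer(dates[span] - ep$mv_day_origin[j])
  }

  # respiratory minima restricted to in-episode measurements
  for (v in c("fio2", "peep")) {
    rows <- m$variable == v
    if (!any(rows)) next
    ts <- m$timestamp[rows]
    vals <- m$value[rows]
    inside <- rep(FALSE, length(ts))
    for (j in seq_len(nrow(ep)))
      inside <- inside | (ts >= ep$start[j] & ts <= ep$end[j])
    res <- daily_min_by_date(ts[inside], vals[inside], v, config, report)
    report <- res$report
    col <- paste0("min_", v)
    hit <- match(names(res$mins), keys)
    sm[[col]][hit] <- unname(res$mins)
  }

  # temperature and WBC extremes, all calendar-day measurements
  trows <- m$variable == "temperature"
  if (any(trows)) {
    keep <- filter_temperature(m$value[trows], config)
    report["excluded_temperature_count"] <-
      report["excluded_temperature_count"] + sum(!keep)
    tv <- m$value[trows][keep]
    td <- format(calendar_date(m$timestamp[trows][keep]), "%Y-%m-%d")
    if (length(tv) > 0) {
      mn <- tapply(tv, td, min)
      mx <- tapply(tv, td, max)
      hit <- match(names(mn), keys)
      sm$min_temp[hit] <- as.numeric(mn)
      sm$max_temp[hit] <- as.numeric(mx)
    }
  }
  wrows <- m$variable == "wbc"
  if (any(wrows)) {
    wv <- m$value[wrows]
    wd <- format(calendar_date(m$timestamp[wrows]), "%Y-%m-%d")
    mn <- tapply(wv, wd, min)
    mx <- tapply(wv, wd, max)
    hit <- match(names(mn), keys)
    sm$min_wbc[hit] <- as.numeric(mn)
    sm$max_wbc[hit] <- as.numeric(mx)
  }

  # antimicrobial starts: given on d but on neither d-1 nor d-2
  if (nrow(ab) > 0) {
    given <- paste(ab$agent, ab$date)
    is_start <- !(paste(ab$agent, ab$date - 1) %in% given) &
      !(paste(ab$agent, ab$date - 2) %in% given)
    st <- ab[is_start, , drop = FALSE]
    if (nrow(st) > 0) {
      joined <- tapply(st$agent, format(st$date, "%Y-%m-%d"),
                       function(a) paste(sort(unique(a)), collapse = ";"))
      hit <- match(names(joined), keys)
      ok <- !is.na(hit)
      sm$new_agents[hit[ok]] <- as.character(joined)[ok]
    }
  }
  list(summaries = sm, report = report)
}
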