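#' Derive mechanical-ventilation episodes from etCO2 continuity
#'
#' The monitors emit an end-tidal CO2 value only while a patient is
#' ventilated, so continuous availability of etCO2 — at least one measurement
#' per 6-minute window — is the proxy for mechanical ventilation. Timestamps
#' are partitioned into maximal runs whose consecutive gaps do not exceed
#' `max_gap_minutes`; each run becomes one episode spanning its first to last
#' timestamp. Duplicate timestamps are ignored.
#'
#' @param timestamps `POSIXct` vector of etCO2 timestamps of one admission
#'   (any order).
#' @param max_gap_minutes Largest within-episode gap, default 6.
#' @return A data frame with columns `start`, `end` (`POSIXct`) and
#'   `mv_day_origin` (`Date`, the calendar day ventilation begins = MV day 1),
#'   one row per episode, time-ordered. Empty input gives zero rows.
#' @export
derive_episodes <- function(timestamps, max_gap_minutes = 6) {
  stopifnot(max_gap_minutes > 0)
  ts <- sort(unique(timestamps))
  if (length(ts) == 0L)
    return(data.frame(start = parse_timestamp(character()),
                      end = parse_timestamp(character()),
                      mv_day_origin = as.Date(character())))
  gaps <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "mins"))
  run <- cumsum(c(TRUE, gaps > max_gap_minutes))
  start <- ts[!duplicated(run)]
  end <- ts[rev(!duplicated(rev(run)))]
  data.frame(start = start, end = end, mv_day_origin = calendar_date(start))
}

#' Merge ventilation episodes separated by short extubation gaps
#'
#' Per the CDC episode convention, reintubation on the same or the next
#' calendar day continues the same ventilation episode and its day numbering.
#' Two consecutive episodes merge when fewer than `merge_gap_days` complete
#' ventilator-free calendar days lie strictly between them; the merged
#' episode spans the union hull and keeps the first component's MV day
#' origin.
#'
#' @param episodes Data frame from [derive_episodes()] (disjoint, ordered).
#' @param merge_gap_days Minimum number of complete free calendar days that
#'   keeps episodes separate, default 1.
#' @return A data frame of merged episodes.
#' @export
merge_adjacent_episodes <- function(episodes, merge_gap_days = 1) {
  n <- nrow(episodes)
  if (n <= 1L) return(episodes)
  keep_start <- 1L
  out <- episodes[0, ]
  for (i in seq_len(n - 1L)) {
    free_days <- as.integer(calendar_date(episodes$start[i + 1L]) -
                              calendar_date(episodes$end[i])) - 1L
    if (max(free_days, 0L) >= merge_gap_days) {
      out <- rbind(out, data.frame(start = episodes$start[keep_start],
                                   end = episodes$end[i],
                                   mv_day_origin = episodes$mv_day_origin[keep_start]))
      keep_start <- i + 1L
    }
  }
  rbind(out, data.frame(start = episodes$start[keep_start],
                        end = episodes$end[n],
                        mv_day_origin = episodes$mv_day_origin[keep_start]))
}

#' Mechanical-ventilation day number of a calendar date
#'
#' MV day 1 is the calendar day ventilation begins; an event may only be
#' declared from MV day 3 onward, so day numbering is load-bearing.
#'
#' @param episode One row of an episode data frame (or a list with
#'   `start`, `end`, `mv_day_origin`).
#' @param date A `Date` within the episode's calendar span.
#' @return Integer day index (1-based).
#' @export
mv_day_index <- function(episode, date) {
  date <- as.Date(date)
  if (date < calendar_date(episode$start) || date > calendar_date(episode$end))
    stop("date outside episode", call. = FALSE)
  1L + as.integer(date - as.Date(episode$mv_day_origin))
}

#' Count ventilator device days by the noon rule
#'
#' An admission contributes one device day on a calendar date when one of its
#' ventilation episodes overlaps that date's noon window (default
#' `[11:00, 13:00)`) by a positive duration; at most one device day per
#' admission and date. Device days are the denominator of VAE incidence.
#'
#' @param episodes Data frame with columns `admission_id`, `start`, `end`
#'   (episodes of all admissions).
#' @param config A [surveillance_config()] supplying `noon_window`.
#' @return A list of class `device_days`: `pairs` (data frame
#'   `admission_id`, `date`), `by_date` (counts per date), `total`.
#' @export
count_device_days <- function(episodes, config = surveillance_config()) {
  config <- as_config(config)
  w <- config$noon_window
  rows <- vector("list", nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    dates <- seq(calendar_date(episodes$start[i]),
                 calendar_date(episodes$end[i]), by = "day")
    w1 <- as.POSIXct(dates, tz = "UTC") + w[1] * 3600
    w2 <- as.POSIXct(dates, tz = "UTC") + w[2] * 3600
    ov <- pmin(as.numeric(episodes$end[i]), as.numeric(w2)) -
      pmax(as.numeric(episodes$start[i]), as.numeric(w1))
    hit <- ov > 0
    if (any(hit))
      rows[[i]] <- data.frame(admission_id = episodes$admission_id[i],
                              date = dates[hit], stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(admission_id = character(), date = as.Date(character()),
                        stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(first_seen_order(pairs$admission_id), pairs$date), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  by_date <- if (nrow(pairs) > 0) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(pairs))),
                            by = list(date = pairs$date), FUN = sum)
    agg[order(agg$date), , drop = FALSE]
  } else data.frame(date = as.Date(character()), n = integer())
  structure(list(pairs = pairs, by_date = by_date, total = nrow(pairs)),
            class = "device_days")
}

#' @export
print.device_days <- function(x, ...) {
  cat(sprintf("%d device days over %d calendar dates (%d admissions)\n",
              x$total, nrow(x$by_date), length(unique(x$pairs$admission_id))))
  invisible(x)
}

# Episodes for every admission in a measurement data frame, merged.
derive_all_episodes <- function(measurements, config) {
  ids <- unique(measurements$admission_id)
  et <- measurements[measurements$variable == "etco2", , drop = FALSE]
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ep <- derive_episodes(et$timestamp[et$admission_id == ids[i]],
                          config$etco2_max_gap_minutes)
    ep <- merge_adjacent_episodes(ep, config$episode_merge_gap_days)
    if (nrow(ep) > 0) ep$admission_id <- ids[i]
    out[[i]] <- ep
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0L)
    return(data.frame(admission_id = character(),
                      start = parse_timestamp(character()),
                      end = parse_timestamp(character()),
                      mv_day_origin = as.Date(character())))
  res <- do.call(rbind, out)
  res[, c("admission_id", "start", "end", "mv_day_origin")]
}
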