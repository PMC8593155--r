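# Fixture builders and independent oracles used across tests.

# Gap-free daily summary table for one admission, ventilated throughout,
# MV day = day index. Value vectors are recycled to n days.
make_summaries <- function(peep = NA, fio2 = NA, min_temp = NA, max_temp = NA,
                           min_wbc = NA, max_wbc = NA, n = NULL,
                           id = "A1", start = as.Date("2010-01-01"),
                           ventilated = TRUE, mv_day = NULL,
                           new_agents = "") {
  if (is.null(n)) n <- max(length(peep), length(fio2), length(ventilated))
  df <- data.frame(admission_id = id, date = start + 0:(n - 1),
                   mv_day = if (is.null(mv_day)) 1:n else mv_day,
                   ventilated = rep_len(ventilated, n),
                   min_fio2 = rep_len(as.numeric(fio2), n),
                   min_peep = rep_len(as.numeric(peep), n),
                   min_temp = rep_len(as.numeric(min_temp), n),
                   max_temp = rep_len(as.numeric(max_temp), n),
                   min_wbc = rep_len(as.numeric(min_wbc), n),
                   max_wbc = rep_len(as.numeric(max_wbc), n),
                   new_agents = rep_len(new_agents, n),
                   stringsAsFactors = FALSE)
  df$mv_day[!df$ventilated] <- NA_integer_
  df
}

# Independent brute-force tier-I detector: evaluates the boolean event
# definition for every day of one admission, then applies the washout
# greedily. Deliberately written as a day-by-day truth table rather than the
# package's incremental scan.
oracle_detect_vac <- function(s, config = surveillance_config()) {
  eps <- 1e-9
  n <- nrow(s)
  tau <- function(crit) {
    thr <- if (crit == "peep") config$peep_increase_threshold
    else config$fio2_increase_threshold
    if (config$tolerance_mode == "shrink_threshold")
      thr * (1 - config$tolerance) else thr
  }
  allowance <- function(crit) {
    thr <- if (crit == "peep") config$peep_increase_threshold
    else config$fio2_increase_threshold
    if (config$tolerance_mode == "baseline_allowance")
      config$tolerance * thr else 0
  }
  fires <- function(i, crit) {
    v <- if (crit == "peep") s$min_peep else s$min_fio2
    if (i < 3 || i + 1 > n) return(FALSE)
    if (is.na(s$mv_day[i]) || s$mv_day[i] < config$earliest_onset_mv_day)
      return(FALSE)
    if (!all(s$ventilated[(i - 2):(i + 1)])) return(FALSE)
    if (any(is.na(v[(i - 2):(i + 1)]))) return(FALSE)
    if (!(v[i - 1] <= v[i - 2] + allowance(crit) + eps)) return(FALSE)
    ref <- if (config$baseline_reference == "first_day") v[i - 2] else v[i - 1]
    (v[i] - ref >= tau(crit) - eps) && (v[i + 1] - ref >= tau(crit) - eps)
  }
  hits <- lapply(seq_len(n), function(i) {
    for (crit in c("peep", "fio2")) if (fires(i, crit)) return(crit)
    NULL
  })
  out <- list()
  next_ok <- as.Date("0001-01-01")
  for (i in seq_len(n)) {
    if (is.null(hits[[i]]) || s$date[i] < next_ok) next
    out[[length(out) + 1]] <- data.frame(
      admission_id = s$admission_id[1], onset_date = s$date[i],
      criterion = hits[[i]], stringsAsFactors = FALSE)
    next_ok <- s$date[i] + config$event_washout_days
  }
  if (length(out) == 0)
    return(data.frame(admission_id = character(),
                      onset_date = as.Date(character()),
                      criterion = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Random small summary sequence for oracle comparison: one ventilation run
# with optional unventilated lead-in/tail, values on coarse grids, sprinkled
# missingness.
random_summaries <- function(n_max = 30) {
  n <- sample(5:n_max, 1)
  lead <- sample(0:2, 1)
  tail_ <- sample(0:2, 1)
  vent <- c(rep(FALSE, lead), rep(TRUE, max(n - lead - tail_, 1)),
            rep(FALSE, tail_))
  n <- length(vent)
  peep <- sample(c(5, 8, 10), n, replace = TRUE)
  fio2 <- sample(c(0.3, 0.4, 0.6, 0.8), n, replace = TRUE)
  peep[runif(n) < 0.1] <- NA
  fio2[runif(n) < 0.1] <- NA
  peep[!vent] <- NA
  fio2[!vent] <- NA
  mv <- rep(NA_integer_, n)
  mv[vent] <- seq_len(sum(vent))
  make_summaries(peep = peep, fio2 = fio2, n = n, ventilated = vent,
                 mv_day = mv)
}

# Minute-scan device-day oracle for one episode.
oracle_device_days <- function(start, end, w = c(11, 13)) {
  m <- seq(start, end, by = 60)
  h <- as.numeric(difftime(m, as.POSIXct(as.Date(m, tz = "UTC"), tz = "UTC"),
                           units = "hours"))
  in_window <- h >= w[1] & h < w[2] & m < end
  length(unique(as.Date(m[in_window], tz = "UTC")))
}

write_measurements_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("admission_id,timestamp,variable,value,source", lines), path)
  path
}

write_antimicrobials_csv <- function(lines,
                                     path = tempfile(fileext = ".csv")) {
  writeLines(c("admission_id,date,agent", lines), path)
  path
}

# Admission-level sensitivity of detected events vs embedded labels.
label_sensitivity <- function(events, labels) {
  if (nrow(labels) == 0) return(NA_real_)
  mean(labels$admission_id %in% events$admission_id)
}
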