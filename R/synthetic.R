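# Seeded synthetic ICU cohort generator.
#
# Emulates a patient-data-management-system export: dense automatic
# measurements (FiO2 and etCO2 every 2 min, PEEP every 15 min), manual
# temperature once per 8 h shift, daily WBC; set-point oscillation noise;
# sporadic downward measurement artefacts; and embedded ground-truth VAC /
# IVAC events defined by construction (set-point trajectories), never by
# re-running the detector.

#' Specification of a synthetic ICU cohort
#'
#' @param n_admissions Number of ventilated admissions.
#' @param vac_fraction Fraction of admissions given an embedded VAC (their
#'   ventilation duration is redrawn until at least 4 days, the minimum an
#'   event needs). Default 0.025 — events occur in about 2.5% of ventilated
#'   admissions.
#' @param ivac_fraction Fraction of embedded VACs upgraded to IVAC (fever or
#'   leukocytosis plus a new agent for 5 days). Default 0.35.
#' @param artefact_rate Per-measurement probability that an FiO2/PEEP value
#'   is replaced by a low spike. Default 0.01.
#' @param artefact_depth Named replacement values of a spike,
#'   `c(fio2 = 0.21, peep = 0)`: FiO2 artefacts drop to ambient air, PEEP
#'   artefacts to zero.
#' @param oscillation_sd Relative SD of measurement noise around the set
#'   point (temperature uses `10 * oscillation_sd` degrees C absolute).
#'   Default 0.02; 0 switches all noise off.
#' @param cadences Measurement intervals in minutes:
#'   `list(fio2 = 2, etco2 = 2, peep = 15, temperature = 480, wbc = 1440)`.
#' @param max_duration Truncation of the ventilation-duration distribution
#'   (days). Default 30.
#' @param start_date First possible admission date. Default `"2008-01-01"`.
#' @param calendar_span_days Admission dates are uniform over this many days.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_admissions = 200,
                        vac_fraction = 0.025,
                        ivac_fraction = 0.35,
                        artefact_rate = 0.01,
                        artefact_depth = c(fio2 = 0.21, peep = 0),
                        oscillation_sd = 0.02,
                        cadences = list(fio2 = 2, etco2 = 2, peep = 15,
                                        temperature = 480, wbc = 1440),
                        max_duration = 30,
                        start_date = "2008-01-01",
                        calendar_span_days = 365,
                        seed = 1L) {
  stopifnot(n_admissions >= 0, vac_fraction >= 0, vac_fraction <= 1,
            ivac_fraction >= 0, ivac_fraction <= 1,
            artefact_rate >= 0, artefact_rate <= 1, oscillation_sd >= 0,
            all(unlist(cadences) > 0), max_duration >= 1)
  structure(list(n_admissions = as.integer(n_admissions),
                 vac_fraction = vac_fraction, ivac_fraction = ivac_fraction,
                 artefact_rate = artefact_rate,
                 artefact_depth = artefact_depth,
                 oscillation_sd = oscillation_sd, cadences = cadences,
                 max_duration = as.integer(max_duration),
                 start_date = as.Date(start_date),
                 calendar_span_days = as.integer(calendar_span_days),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Ventilation duration in calendar days: discrete head P(1)=.55, P(2)=.15,
# P(3)=.12 with a geometric tail (ratio .75) over 4..max. Median 1 and
# quartiles 1 and 3 — matching short-stay ICU ventilation (median 1, IQR
# 1-3) — with the quantiles safely away from the .5/.75 knife edges so
# finite samples reproduce them. A pure geometric cannot hit both the
# median and the upper quartile.
rvent_duration <- function(n, max_duration = 30) {
  tail_w <- 0.75^(seq_len(max_duration - 3) - 1)
  probs <- c(0.55, 0.15, 0.12, 0.18 * tail_w / sum(tail_w))
  sample.int(max_duration, n, replace = TRUE, prob = probs)
}

round_to <- function(x, resolution) round(x / resolution) * resolution

#' Generate one synthetic admission
#'
#' Builds set-point trajectories (baseline FiO2 in 0.30-0.50, PEEP in
#' {5, 6, 8}), holds them stable, and — for an embedded event — raises PEEP
#' by >= 3 cmH2O or FiO2 by >= 0.20 from a random onset at MV day >= 3,
#' sustained to the end of ventilation. Measurements are sampled at the spec
#' cadences with oscillation noise and device resolution (FiO2 0.01, PEEP
#' 0.5 cmH2O, temperature and WBC 0.1); etCO2 timestamps cover exactly the
#' intended ventilation episode with 2-minute gaps. IVAC admissions
#' additionally get a fever or leukocytosis day within 1 day of onset and a
#' new antimicrobial agent administered for 5 consecutive days starting
#' within the same window. Draws from the current RNG stream.
#'
#' @param id Admission identifier.
#' @param spec A [cohort_spec()].
#' @param embed `"none"`, `"vac"` or `"ivac"`.
#' @return List with `measurements`, `antimicrobials`, `label` (one-row data
#'   frame or `NULL`) and `redraws` (durations redrawn to fit the event).
#' @export
generate_admission <- function(id, spec, embed = c("none", "vac", "ivac")) {
  embed <- match.arg(embed)
  D <- rvent_duration(1, spec$max_duration)
  redraws <- 0L
  while (embed != "none" && D < 4L) {
    D <- rvent_duration(1, spec$max_duration)
    redraws <- redraws + 1L
  }
  day1 <- spec$start_date + sample.int(spec$calendar_span_days, 1L) - 1L
  day1_ts <- as.POSIXct(day1, tz = "UTC")
  start <- day1_ts + round(stats::runif(1, 6, 12) * 3600)
  end <- if (D == 1L) start + round(stats::runif(1, 2, 10) * 3600)
  else as.POSIXct(day1 + (D - 1L), tz = "UTC") +
    round(stats::runif(1, 10, 18) * 3600)

  f0 <- sample(seq(0.30, 0.50, by = 0.05), 1L)
  p0 <- sample(c(5, 6, 8), 1L)
  fio2_set <- rep(f0, D)
  peep_set <- rep(p0, D)
  temp_set <- rep(37.0, D)
  wbc_set <- rep(8.0, D)

  label <- NULL
  antimicrobials <- data.frame(admission_id = character(),
                               date = as.Date(character()),
                               agent = character(), stringsAsFactors = FALSE)
  if (embed != "none") {
    onset <- if (D == 4L) 3L else sample(3:(D - 1L), 1L)
    criterion <- sample(c("peep", "fio2"), 1L)
    if (criterion == "peep") {
      peep_set[onset:D] <- p0 + sample(3:5, 1L)
    } else {
      fio2_set[onset:D] <- f0 + sample(c(0.20, 0.25, 0.30), 1L)
    }
    tier <- "VAC"
    if (embed == "ivac") {
      tier <- "IVAC"
      sign_day <- min(max(onset + sample(-1:1, 1L), 1L), D)
      if (sample(c(TRUE, FALSE), 1L)) temp_set[sign_day] <- 38.6
      else wbc_set[sign_day] <- 14.5
      agent <- sample(c("ceftriaxone", "piperacillin-tazobactam",
                        "meropenem", "cefepime"), 1L)
      ab_start <- max(onset + sample(-1:1, 1L), 1L)
      antimicrobials <- data.frame(
        admission_id = id, date = day1 + (ab_start - 1L) + 0:4,
        agent = agent, stringsAsFactors = FALSE)
    }
    label <- data.frame(admission_id = id, onset_date = day1 + (onset - 1L),
                        tier = tier, criterion = criterion,
                        stringsAsFactors = FALSE)
  }

  osc <- spec$oscillation_sd
  sample_series <- function(variable, cadence_min, set_by_day, resolution,
                            noise_fun, source) {
    ts <- seq(start, end, by = cadence_min * 60)
    day_idx <- pmin(pmax(as.integer(calendar_date(ts) - day1) + 1L, 1L), D)
    base <- set_by_day[day_idx]
    value <- round_to(noise_fun(base), resolution)
    data.frame(admission_id = id, timestamp = ts, variable = variable,
               value = value, source = source, stringsAsFactors = FALSE)
  }
  rel_noise <- function(base) base * (1 + stats::rnorm(length(base), 0, osc))
  abs_noise <- function(base) base + stats::rnorm(length(base), 0, 10 * osc)

  measurements <- rbind(
    sample_series("etco2", spec$cadences$etco2, rep(35, D), 1,
                  function(b) b, "monitor"),
    sample_series("fio2", spec$cadences$fio2, fio2_set, 0.01, rel_noise,
                  "monitor"),
    sample_series("peep", spec$cadences$peep, peep_set, 0.5, rel_noise,
                  "monitor"),
    sample_series("temperature", spec$cadences$temperature, temp_set, 0.1,
                  abs_noise, "tympanic"),
    sample_series("wbc", spec$cadences$wbc, wbc_set, 0.1, rel_noise, "lab"))

  list(measurements = measurements, antimicrobials = antimicrobials,
       label = label, redraws = redraws)
}

#' Inject downward measurement artefacts
#'
#' Each FiO2/PEEP measurement is independently replaced by a low spike with
#' probability `rate` (spike count is Binomial), emulating the sporadic
#' incorrect low readings that distort recorded daily minima. Only downward
#' spikes are modelled — only they can influence the lowest daily value.
#' Draws from the current RNG stream; at `rate = 0` the stream is returned
#' unchanged.
#'
#' @param measurements A measurement data frame.
#' @param rate Per-measurement spike probability.
#' @param depth Named replacement values, default `c(fio2 = 0.21, peep = 0)`.
#' @return The measurement data frame with spikes applied.
#' @export
inject_artifacts <- function(measurements, rate,
                             depth = c(fio2 = 0.21, peep = 0)) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(measurements)
  for (v in intersect(names(depth), c("fio2", "peep"))) {
    rows <- which(measurements$variable == v)
    hit <- rows[stats::runif(length(rows)) < rate]
    measurements$value[hit] <- depth[[v]]
  }
  measurements
}

#' Generate a full synthetic cohort
#'
#' Draws every admission from a seeded RNG: embedded-event assignment
#' (`round(vac_fraction * n)` admissions, of which
#' `round(ivac_fraction * n_vac)` are IVAC), per-admission streams, then
#' artefact injection. Optionally writes the three pipeline input files
#' (`measurements.csv`, `antimicrobials.csv`, `truth_labels.csv`).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory for the CSV files, or `NULL` for in-memory
#'   only.
#' @return Invisibly, a list: `measurements`, `antimicrobials`, `labels`,
#'   `log` (embedded event counts and duration redraws).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  n <- spec$n_admissions
  n_vac <- round(spec$vac_fraction * n)
  n_ivac <- round(spec$ivac_fraction * n_vac)
  embed <- rep("none", n)
  if (n_vac > 0) {
    vac_ids <- sample.int(n, n_vac)
    embed[vac_ids] <- "vac"
    if (n_ivac > 0) embed[sample(vac_ids, n_ivac)] <- "ivac"
  }
  ms <- vector("list", n)
  abs_ <- vector("list", n)
  labels <- vector("list", n)
  redraws <- 0L
  for (i in seq_len(n)) {
    adm <- generate_admission(sprintf("A%04d", i), spec, embed[i])
    ms[[i]] <- adm$measurements
    abs_[[i]] <- adm$antimicrobials
    labels[[i]] <- adm$label
    redraws <- redraws + adm$redraws
  }
  empty_m <- data.frame(admission_id = character(),
                        timestamp = parse_timestamp(character()),
                        variable = character(), value = numeric(),
                        source = character(), stringsAsFactors = FALSE)
  measurements <- do.call(rbind, c(ms, list(empty_m)))
  measurements <- inject_artifacts(measurements, spec$artefact_rate,
                                   spec$artefact_depth)
  antimicrobials <- do.call(rbind, c(abs_, list(
    data.frame(admission_id = character(), date = as.Date(character()),
               agent = character(), stringsAsFactors = FALSE))))
  labels <- do.call(rbind, c(labels, list(
    data.frame(admission_id = character(), onset_date = as.Date(character()),
               tier = character(), criterion = character(),
               stringsAsFactors = FALSE))))
  rownames(measurements) <- rownames(antimicrobials) <- rownames(labels) <- NULL
  log <- c(n_admissions = n, n_vac_embedded = nrow(labels),
           n_ivac_embedded = sum(labels$tier == "IVAC"),
           duration_redraws = redraws)
  out <- list(measurements = measurements, antimicrobials = antimicrobials,
              labels = labels, log = log)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mm <- measurements
    mm$timestamp <- format(mm$timestamp, "%Y-%m-%dT%H:%M:%S")
    write_plain_csv(mm, file.path(dir, "measurements.csv"))
    aa <- antimicrobials
    aa$date <- format(aa$date, "%Y-%m-%d")
    write_plain_csv(aa, file.path(dir, "antimicrobials.csv"))
    ll <- labels
    ll$onset_date <- format(ll$onset_date, "%Y-%m-%d")
    write_plain_csv(ll, file.path(dir, "truth_labels.csv"))
  }
  invisible(out)
}
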