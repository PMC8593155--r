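# Pipeline commands: the shell entry point (inst/cli/vaevent.R) is a thin
# wrapper over these functions.

pkg_version <- function() as.character(utils::packageVersion("vaesurv"))

make_manifest <- function(command, config, paths, counts, elapsed) {
  list(command = command, tool_version = pkg_version(),
       config = unclass(config), paths = paths, counts = as.list(counts),
       wall_time_s = round(elapsed, 3),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the full detection pipeline
#'
#' Read (or accept in-memory) measurement and antimicrobial data, derive and
#' merge ventilation episodes, build cleaned daily summaries, and detect
#' tier I/II events. With `out_dir` set, writes `events.csv`,
#' `daily_summary.csv`, `episodes.csv` and `manifest.json`.
#'
#' @param measurements Path to `measurements.csv` or a measurement data
#'   frame.
#' @param antimicrobials Path to `antimicrobials.csv` or a data frame (may
#'   be `NULL` for none).
#' @param config A [surveillance_config()], YAML path, or named list.
#' @param out_dir Optional output directory.
#' @return List: `events`, `summaries`, `episodes`, `device_days`,
#'   `cleaning_report`, `manifest`.
#' @export
run_detect <- function(measurements, antimicrobials = NULL,
                       config = surveillance_config(), out_dir = NULL) {
  t0 <- proc.time()["elapsed"]
  config <- as_config(config)
  m_path <- if (is.character(measurements)) measurements else NA
  if (is.character(measurements))
    measurements <- read_measurements(measurements, config)
  a_path <- if (is.character(antimicrobials)) antimicrobials else NA
  if (is.character(antimicrobials))
    antimicrobials <- read_antimicrobials(antimicrobials)
  if (is.null(antimicrobials))
    antimicrobials <- data.frame(admission_id = character(),
                                 date = as.Date(character()),
                                 agent = character(), stringsAsFactors = FALSE)
  episodes <- derive_all_episodes(measurements, config)
  summaries <- build_daily_summaries(measurements, episodes, antimicrobials,
                                     config)
  events <- detect_vae(summaries, antimicrobials, config)
  dd <- count_device_days(episodes, config)
  counts <- c(measurement_rows = nrow(measurements),
              admissions = length(unique(measurements$admission_id)),
              episodes = nrow(episodes), summary_days = nrow(summaries),
              device_days = dd$total, events = nrow(events),
              ivac_events = sum(events$tier == "IVAC"))
  manifest <- make_manifest("detect", config,
                            list(measurements = m_path,
                                 antimicrobials = a_path,
                                 out_dir = out_dir %||% NA),
                            counts, proc.time()["elapsed"] - t0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_events(events, file.path(out_dir, "events.csv"))
    write_daily_summaries(summaries, file.path(out_dir, "daily_summary.csv"))
    ep <- episodes
    ep$start <- format(ep$start, "%Y-%m-%dT%H:%M:%S")
    ep$end <- format(ep$end, "%Y-%m-%dT%H:%M:%S")
    write_plain_csv(ep[c("admission_id", "start", "end")],
                    file.path(out_dir, "episodes.csv"))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(events = events, summaries = summaries, episodes = episodes,
       device_days = dd, cleaning_report = cleaning_report(summaries),
       manifest = manifest)
}

#' Validate detected events against ground truth
#'
#' Compares admissions flagged event-positive by the detector against the
#' gold-standard labels over a common admission universe, at the VAC level
#' (any event) and the IVAC level (tier-II events).
#'
#' @param events Events data frame or path to `events.csv`.
#' @param truth Truth data frame (`admission_id`, `tier`, ...) or path to
#'   `truth_labels.csv`.
#' @param universe Character vector of all admission ids under surveillance.
#' @param out_json Optional path for a JSON metrics report.
#' @return List with per-level `confusion_matrix` and `vae_metrics`.
#' @export
run_validate <- function(events, truth, universe, out_json = NULL) {
  if (is.character(events)) events <- read_events(events)
  if (is.character(truth)) {
    raw <- utils::read.csv(truth, colClasses = "character",
                           stringsAsFactors = FALSE)
    raw$onset_date <- parse_date(raw$onset_date)
    truth <- raw
  }
  level_sets <- function(df, level) {
    if (level == "VAC") unique(df$admission_id)
    else unique(df$admission_id[df$tier == "IVAC"])
  }
  out <- list()
  for (level in c("VAC", "IVAC")) {
    cm <- compare_event_sets(level_sets(truth, level),
                             level_sets(events, level), universe)
    out[[level]] <- list(cm = cm, metrics = classification_metrics(cm))
  }
  if (!is.null(out_json)) {
    rep <- lapply(out, function(x)
      c(unclass(x$cm), as.list(x$metrics$values)))
    jsonlite::write_json(rep, out_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  out
}

#' Incidence rates and yearly trend
#'
#' Either recomputes device days from raw measurements by the noon rule and
#' groups detected events by onset year, or accepts a pre-tabulated
#' `(label, events, device_days)` table (e.g. a published yearly table).
#' Produces per-group incidence with exact Poisson intervals, the overall
#' rate, and — with at least 3 groups — the Poisson log-linear trend.
#'
#' @param events Events data frame / `events.csv` path, or `NULL` when
#'   `table` is given.
#' @param measurements Measurement data frame / path used to recompute
#'   device days (ignored when `table` is given).
#' @param table Optional pre-tabulated data frame with `label` (or `year`),
#'   `events`, `device_days`.
#' @param config A [surveillance_config()].
#' @param out_dir Optional directory for `incidence.csv` and `trend.json`.
#' @return List: `incidence` (per-group + overall rows), `trend`
#'   (`vae_trend` or `NULL` with fewer than 3 groups).
#' @export
run_incidence <- function(events = NULL, measurements = NULL, table = NULL,
                          config = surveillance_config(), out_dir = NULL) {
  config <- as_config(config)
  if (is.null(table)) {
    if (is.character(events)) events <- read_events(events)
    if (is.character(measurements))
      measurements <- read_measurements(measurements, config)
    episodes <- derive_all_episodes(measurements, config)
    dd <- count_device_days(episodes, config)
    dd_year <- table(format(dd$pairs$date, "%Y"))
    ev_year <- table(format(events$onset_date, "%Y"))
    years <- sort(names(dd_year))
    table <- data.frame(label = years,
                        events = as.integer(ev_year[years]),
                        device_days = as.integer(dd_year[years]),
                        stringsAsFactors = FALSE)
    table$events[is.na(table$events)] <- 0L
  }
  if (!"label" %in% names(table)) table$label <- table$year
  rows <- do.call(rbind, lapply(seq_len(nrow(table)), function(i)
    incidence_rate(table$events[i], table$device_days[i], table$label[i])))
  overall <- incidence_rate(sum(table$events), sum(table$device_days),
                            "overall")
  incidence <- rbind(rows, overall)
  trend <- NULL
  if (nrow(table) >= 3) {
    trend <- poisson_trend(table)
  } else {
    message("fewer than 3 groups: trend skipped")
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_plain_csv(incidence, file.path(out_dir, "incidence.csv"))
    if (!is.null(trend))
      jsonlite::write_json(
        list(coefficients = as.list(trend$coefficients), irr = trend$irr,
             ci_low = trend$ci_low, ci_high = trend$ci_high,
             p_value = trend$p_value, p_lrt = trend$p_lrt,
             iterations = trend$iterations, converged = trend$converged),
        file.path(out_dir, "trend.json"), auto_unbox = TRUE, digits = NA)
  }
  list(incidence = incidence, trend = trend)
}

#' Simulate a cohort and write pipeline input files
#'
#' Thin wrapper over [generate_cohort()] for the command-line pipeline.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @return Invisibly, the generator output (see [generate_cohort()]).
#' @export
run_simulate <- function(spec, dir) {
  generate_cohort(spec, dir)
}
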