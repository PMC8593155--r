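#' Read raw ICU measurement streams
#'
#' Reads the `measurements.csv` dialect: columns `admission_id, timestamp,
#' variable, value, source` with ISO 8601 timestamps and `variable` one of
#' `etco2`, `fio2`, `peep`, `temperature`, `wbc`. FiO2 entered as a percent
#' (value > 1) is normalised to a fraction. Malformed rows (unparseable
#' timestamp, unknown variable, non-finite value) are counted, reported via a
#' warning, and skipped; a missing required column is a hard error.
#'
#' @param path Path to a CSV file.
#' @param config A [surveillance_config()] (unused thresholds are accepted for
#'   interface symmetry; only unit normalisation happens here).
#' @return A data frame of measurements sorted by admission (first-seen
#'   order) and timestamp, with an attribute `"read_log"` holding per-category
#'   drop/normalisation counts.
#' @export
read_measurements <- function(path, config = surveillance_config()) {
  config <- as_config(config)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("admission_id", "timestamp", "variable", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"source" %in% names(raw)) raw$source <- ""

  log <- c(bad_timestamp = 0L, bad_variable = 0L, bad_value = 0L,
           fio2_percent_normalized = 0L)
  if (nrow(raw) == 0L) {
    out <- data.frame(admission_id = character(), timestamp = parse_timestamp(character()),
                      variable = character(), value = numeric(),
                      source = character(), stringsAsFactors = FALSE)
    attr(out, "read_log") <- log
    return(out)
  }

  ts <- parse_timestamp(raw$timestamp)
  variable <- tolower(trimws(raw$variable))
  value <- suppressWarnings(as.numeric(raw$value))

  ok_ts <- !is.na(ts)
  ok_var <- variable %in% c("etco2", "fio2", "peep", "temperature", "wbc")
  ok_val <- is.finite(value)
  log["bad_timestamp"] <- sum(!ok_ts)
  log["bad_variable"] <- sum(ok_ts & !ok_var)
  log["bad_value"] <- sum(ok_ts & ok_var & !ok_val)
  keep <- ok_ts & ok_var & ok_val
  dropped <- sum(!keep)
  if (dropped > 0)
    warning(sprintf("dropped %d malformed measurement row(s) (%s)", dropped,
                    paste(names(log)[1:3], log[1:3], sep = "=",
                          collapse = ", ")), call. = FALSE)

  out <- data.frame(admission_id = raw$admission_id[keep],
                    timestamp = ts[keep],
                    variable = variable[keep],
                    value = value[keep],
                    source = raw$source[keep],
                    stringsAsFactors = FALSE)

  pct <- out$variable == "fio2" & out$value > 1
  if (any(pct)) {
    out$value[pct] <- out$value[pct] / 100
    log["fio2_percent_normalized"] <- sum(pct)
  }

  out <- out[order(first_seen_order(out$admission_id), out$timestamp), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "read_log") <- log
  out
}

#' Read antimicrobial administration records
#'
#' Reads the `antimicrobials.csv` dialect (`admission_id, date, agent`).
#' Agent names are case-folded and whitespace-trimmed; duplicate
#' (admission, date, agent) rows collapse to one.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `admission_id`, `date` (`Date`),
#'   `agent`, one row per administration day, with a `"read_log"` attribute.
#' @export
read_antimicrobials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("admission_id", "date", "agent")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  log <- c(bad_date = 0L, duplicates_collapsed = 0L)
  if (nrow(raw) == 0L) {
    out <- data.frame(admission_id = character(), date = as.Date(character()),
                      agent = character(), stringsAsFactors = FALSE)
    attr(out, "read_log") <- log
    return(out)
  }
  d <- parse_date(raw$date)
  agent <- tolower(trimws(raw$agent))
  keep <- !is.na(d) & nzchar(agent)
  log["bad_date"] <- sum(!keep)
  if (log["bad_date"] > 0)
    warning(sprintf("dropped %d malformed antimicrobial row(s)",
                    log["bad_date"]), call. = FALSE)
  out <- data.frame(admission_id = raw$admission_id[keep], date = d[keep],
                    agent = agent[keep], stringsAsFactors = FALSE)
  dup <- duplicated(out[c("admission_id", "date", "agent")])
  log["duplicates_collapsed"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  out <- out[order(first_seen_order(out$admission_id), out$date, out$agent), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "read_log") <- log
  out
}

# Shared plain-CSV writer: unquoted, NA as empty, full numeric precision,
# so that write -> read -> write is byte-identical.
write_plain_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- vapply(df[[j]], function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE),
    character(1))
  utils::write.table(df, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write and read detected events
#'
#' `write_events()` writes the canonical `events.csv` dialect (columns
#' `admission_id, onset_date, tier, criterion, baseline_value,
#' worsening_value, mv_day`) in stable (admission, onset date) order;
#' `read_events()` reads it back losslessly.
#'
#' @param events A data frame of events as produced by [detect_vae()].
#' @param path Output (input) CSV path.
#' @return `write_events()` returns the path invisibly; `read_events()` a
#'   data frame of events.
#' @export
write_events <- function(events, path) {
  cols <- c("admission_id", "onset_date", "tier", "criterion",
            "baseline_value", "worsening_value", "mv_day")
  if (nrow(events) == 0L) {
    empty <- data.frame(matrix(character(), ncol = length(cols),
                               dimnames = list(NULL, cols)))
    utils::write.table(empty, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(path))
  }
  out <- events[order(first_seen_order(events$admission_id),
                      events$onset_date), cols, drop = FALSE]
  out$onset_date <- format(out$onset_date, "%Y-%m-%d")
  out$mv_day <- as.integer(out$mv_day)
  write_plain_csv(out, path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  data.frame(admission_id = raw$admission_id,
             onset_date = parse_date(raw$onset_date),
             tier = raw$tier,
             criterion = raw$criterion,
             baseline_value = as.numeric(raw$baseline_value),
             worsening_value = as.numeric(raw$worsening_value),
             mv_day = as.integer(raw$mv_day),
             stringsAsFactors = FALSE)
}

#' Write daily ventilator summaries to CSV
#'
#' Columns follow the `daily_summary.csv` dialect; absent values are written
#' empty, new agents semicolon-joined.
#'
#' @param summaries Output of [build_daily_summaries()].
#' @param path Output CSV path.
#' @export
write_daily_summaries <- function(summaries, path) {
  out <- summaries
  out$date <- format(out$date, "%Y-%m-%d")
  out$ventilated <- ifelse(out$ventilated, "true", "false")
  names(out)[names(out) == "new_agents"] <- "new_agents"
  write_plain_csv(out, path)
}
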