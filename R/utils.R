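# Internal helpers shared across modules.

# Timestamps are naive local clock time; POSIXct/UTC is used as the carrier so
# day arithmetic is free of DST artefacts. Accepts ISO 8601 with "T" or space
# separator, seconds optional. Unparseable entries come back NA.
parse_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

parse_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")

calendar_date <- function(ts) as.Date(ts, tz = "UTC")

# Round half away from zero (base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# Order admission ids by first appearance so grouping never silently reorders.
first_seen_order <- function(ids) match(ids, unique(ids))
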