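#' Confusion matrix for surveillance validation
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  for (v in list(tp, fp, fn, tn))
    if (!is_count(v)) stop("cells must be non-negative integers",
                           call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values `tp/(tp+fp)` and `tn/(tn+fn)`. A metric with a zero
#' denominator is undefined and reported as `NA`, never fabricated. The
#' `rounded` element carries the two-decimal display values (half away from
#' zero), matching surveillance-report convention.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `vae_metrics`: list with `values` (exact),
#'   `rounded`, `undefined` (names of undefined metrics), `cm`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp + cm$fn + cm$tn == 0L)
    stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  values <- c(sensitivity = ratio(cm$tp, cm$tp + cm$fn),
              specificity = ratio(cm$tn, cm$tn + cm$fp),
              ppv = ratio(cm$tp, cm$tp + cm$fp),
              npv = ratio(cm$tn, cm$tn + cm$fn))
  structure(list(values = values,
                 rounded = round_half_away(values, 2),
                 undefined = names(values)[is.na(values)],
                 cm = cm),
            class = "vae_metrics")
}

#' @export
print.vae_metrics <- function(x, ...) {
  v <- x$rounded
  fmt <- function(u) ifelse(is.na(u), "undefined", sprintf("%.2f", u))
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(v["sensitivity"]), fmt(v["specificity"]),
              fmt(v["ppv"]), fmt(v["npv"])))
  invisible(x)
}

#' Confusion matrix from labelled unit sets
#'
#' Compares predicted event-positive units (e.g. admissions) against the
#' gold-standard set over a common universe, by set algebra on unit keys.
#'
#' @param truth,predicted Character vectors of positive unit keys.
#' @param universe Character vector of all unit keys under surveillance.
#' @return A [confusion_matrix()].
#' @export
compare_event_sets <- function(truth, predicted, universe) {
  truth <- unique(as.character(truth))
  predicted <- unique(as.character(predicted))
  universe <- unique(as.character(universe))
  outside <- setdiff(union(truth, predicted), universe)
  if (length(outside) > 0)
    stop("unit(s) outside universe: ", paste(utils::head(outside, 5),
                                             collapse = ", "), call. = FALSE)
  tp <- length(intersect(truth, predicted))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  confusion_matrix(tp, fp, fn, tn)
}

#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' Two-sided interval for a Poisson count over an exposure, expressed per
#' 1000 exposure units, via chi-square quantiles:
#' `low = qchisq(alpha/2, 2k)/2` and `high = qchisq(1-alpha/2, 2k+2)/2`,
#' divided by the exposure (lower bound 0 when the count is 0).
#'
#' @param count Non-negative event count.
#' @param exposure Positive exposure (e.g. ventilator days).
#' @param level Confidence level, default 0.95.
#' @return `c(low, high)` per 1000 exposure units.
#' @export
exact_poisson_ci <- function(count, exposure, level = 0.95) {
  stopifnot(is_count(count), exposure > 0, level > 0, level < 1)
  alpha <- 1 - level
  low <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  c(low = low / exposure * 1000, high = high / exposure * 1000)
}

#' Incidence rate per 1000 device days
#'
#' @param events Event count.
#' @param device_days Positive ventilator-day denominator.
#' @param label Optional stratum label (e.g. a year).
#' @param level Confidence level for the exact Poisson interval.
#' @return One-row data frame: `label`, `events`, `device_days`,
#'   `rate_per_1000` (exact; display convention is one decimal), `ci_low`,
#'   `ci_high`.
#' @export
incidence_rate <- function(events, device_days, label = NA, level = 0.95) {
  if (!is.numeric(device_days) || device_days <= 0)
    stop("device_days must be positive", call. = FALSE)
  stopifnot(is_count(events))
  ci <- exact_poisson_ci(events, device_days, level)
  data.frame(label = label, events = as.integer(events),
             device_days = device_days,
             rate_per_1000 = 1000 * events / device_days,
             ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
             stringsAsFactors = FALSE)
}

#' Yearly incidence trend by Poisson regression
#'
#' Fits the log-linear model `log E[events_i] = b0 + b1 * year_i +
#' log(device_days_i)` with year as a continuous covariate and the exposure
#' as offset, by iteratively reweighted least squares (relative deviance
#' change below 1e-10, at most 100 iterations). The exponentiated slope is
#' the yearly incidence rate ratio (IRR); the interval and p-value are Wald,
#' with a likelihood-ratio p also reported.
#'
#' @param yearly Data frame with columns `year` (or `label`), `events`,
#'   `device_days`; at least 3 rows.
#' @param level Confidence level, default 0.95.
#' @return Object of class `vae_trend`: `coefficients` (intercept, slope on
#'   the log scale), `irr`, `ci_low`, `ci_high`, `p_value`, `p_lrt`, `se`,
#'   `converged`, `iterations`, `data`.
#' @export
poisson_trend <- function(yearly, level = 0.95) {
  if (!is.data.frame(yearly)) yearly <- as.data.frame(yearly)
  if (!"year" %in% names(yearly) && "label" %in% names(yearly))
    yearly$year <- as.numeric(yearly$label)
  stopifnot(all(c("year", "events", "device_days") %in% names(yearly)))
  if (nrow(yearly) < 3) stop("need at least 3 years for a trend",
                             call. = FALSE)
  if (any(yearly$device_days <= 0))
    stop("device_days must be positive in every year", call. = FALSE)
  fit <- stats::glm(events ~ year + offset(log(device_days)),
                    family = stats::poisson(), data = yearly,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in %d iterations", fit$iter),
         call. = FALSE)
  co <- summary(fit)$coefficients
  slope <- co["year", "Estimate"]
  se <- co["year", "Std. Error"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  null_fit <- stats::glm(events ~ 1 + offset(log(device_days)),
                         family = stats::poisson(), data = yearly)
  p_lrt <- stats::pchisq(null_fit$deviance - fit$deviance, df = 1,
                         lower.tail = FALSE)
  structure(list(coefficients = c(intercept = unname(co["(Intercept)",
                                                        "Estimate"]),
                                  slope = unname(slope)),
                 irr = exp(slope),
                 ci_low = exp(slope - z * se),
                 ci_high = exp(slope + z * se),
                 p_value = co["year", "Pr(>|z|)"],
                 p_lrt = p_lrt,
                 se = se,
                 converged = fit$converged,
                 iterations = fit$iter,
                 level = level,
                 data = yearly,
                 fit = fit),
            class = "vae_trend")
}

#' @export
print.vae_trend <- function(x, ...) {
  cat(sprintf(
    "Poisson trend over %d years: IRR %.2f per year (%.0f%% CI %.2f-%.2f), p = %.2g\n",
    nrow(x$data), round_half_away(x$irr, 2), 100 * x$level,
    round_half_away(x$ci_low, 2), round_half_away(x$ci_high, 2), x$p_value))
  cat(sprintf("IRLS converged in %d iterations\n", x$iterations))
  invisible(x)
}

#' @export
coef.vae_trend <- function(object, ...) object$coefficients

#' @export
confint.vae_trend <- function(object, parm = "irr", level = NULL, ...) {
  c(low = object$ci_low, high = object$ci_high)
}
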