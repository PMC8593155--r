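test_that("classification metrics reproduce published validation rows", {
  m1 <- classification_metrics(confusion_matrix(42, 0, 1, 89))
  expect_equal(unname(m1$rounded["sensitivity"]), 0.98)
  expect_equal(unname(m1$rounded["specificity"]), 1.00)
  expect_equal(unname(m1$rounded["ppv"]), 1.00)
  expect_equal(unname(m1$rounded["npv"]), 0.99)

  m2 <- classification_metrics(confusion_matrix(29, 2, 4, 65))
  expect_equal(unname(m2$rounded), c(0.88, 0.97, 0.94, 0.94),
               ignore_attr = TRUE)

  m3 <- classification_metrics(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(m3$values["sensitivity"]))
  expect_true("sensitivity" %in% m3$undefined)
  expect_equal(unname(m3$values["specificity"]), 1.00)
})

test_that("metrics agree with direct arithmetic on degenerate patterns", {
  for (tp in 0:1) for (fp in 0:1) for (fn in 0:1) for (tn in 0:1) {
    if (tp + fp + fn + tn == 0) next
    m <- classification_metrics(confusion_matrix(tp, fp, fn, tn))
    direct <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_equal(unname(m$values),
                 c(direct(tp, tp + fn), direct(tn, tn + fp),
                   direct(tp, tp + fp), direct(tn, tn + fn)))
  }
})

test_that("event-set comparison matches brute-force membership counts", {
  universe <- sprintf("U%03d", 1:50)
  cm0 <- compare_event_sets(character(), character(), universe)
  expect_equal(cm0$tn, 50L)
  cm1 <- compare_event_sets(universe[1:5], universe[1:5], universe)
  expect_equal(c(cm1$fp, cm1$fn), c(0L, 0L))

  set.seed(53)
  big <- sprintf("U%03d", 1:100)
  for (i in 1:20) {
    truth <- sample(big, sample(0:40, 1))
    pred <- sample(big, sample(0:40, 1))
    cm <- compare_event_sets(truth, pred, big)
    expect_equal(cm$tp, sum(big %in% truth & big %in% pred))
    expect_equal(cm$fp, sum(!(big %in% truth) & big %in% pred))
    expect_equal(cm$fn, sum(big %in% truth & !(big %in% pred)))
    expect_equal(cm$tn, sum(!(big %in% truth) & !(big %in% pred)))
  }
  expect_error(compare_event_sets("X1", character(), universe), "outside")
})

test_that("incidence rates are per 1000 device days and scale invariant", {
  expect_equal(round(incidence_rate(592, 37221)$rate_per_1000, 1), 15.9)
  expect_equal(round(incidence_rate(94, 4251)$rate_per_1000, 1), 22.1)
  expect_equal(incidence_rate(0, 500)$rate_per_1000, 0)
  expect_error(incidence_rate(5, 0), "positive")
  r1 <- incidence_rate(40, 4000)$rate_per_1000
  r3 <- incidence_rate(120, 12000)$rate_per_1000
  expect_equal(r1, r3)
})

test_that("exact Poisson interval matches tail-probability inversion", {
  expect_equal(unname(exact_poisson_ci(0, 100)["low"]), 0)
  # independent oracle: invert the Poisson tail probabilities numerically
  oracle_ci <- function(k, expo, level = 0.95) {
    a <- (1 - level) / 2
    low <- if (k == 0) 0 else
      uniroot(function(mu) 1 - ppois(k - 1, mu) - a, c(1e-9, 10 * k + 50),
              tol = 1e-10)$root
    high <- uniroot(function(mu) ppois(k, mu) - a, c(1e-9, 10 * k + 100),
                    tol = 1e-10)$root
    c(low, high) / expo * 1000
  }
  for (k in c(1, 5, 26, 100)) {
    got <- exact_poisson_ci(k, 10000)
    expect_equal(unname(got), oracle_ci(k, 10000), tolerance = 1e-6)
  }
  ci <- exact_poisson_ci(100, 10000)
  expect_lt(ci["low"], 10)
  expect_gt(ci["high"], 10)
})

table3 <- utils::read.csv(system.file("extdata", "example_yearly_vae.csv",
                                      package = "vaesurv"))

test_that("Poisson trend reproduces the published yearly rate ratios", {
  fit <- poisson_trend(table3)
  expect_equal(round(fit$irr, 2), 0.96)
  expect_equal(round(fit$ci_low, 2), 0.93)
  expect_equal(round(fit$ci_high, 2), 1.00)
  expect_equal(round(fit$p_value, 2), 0.03)
  expect_true(fit$converged)

  sub <- poisson_trend(table3[table3$year %in% 2009:2015, ])
  expect_equal(round(sub$irr, 2), 1.01)
  expect_equal(round(sub$ci_low, 2), 0.97)
  expect_equal(round(sub$ci_high, 2), 1.06)
  expect_equal(round(sub$p_value, 2), 0.61)
})

test_that("a flat cohort yields a unit rate ratio and zero slope", {
  flat <- data.frame(year = 2010:2014, events = 50, device_days = 4000)
  fit <- poisson_trend(flat)
  expect_equal(fit$irr, 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["slope"]), 0, tolerance = 1e-8)
})

test_that("trend fit zeroes the Poisson score equations", {
  fit <- poisson_trend(table3)
  mu <- exp(coef(fit)["intercept"] + coef(fit)["slope"] * table3$year +
              log(table3$device_days))
  expect_lt(abs(sum(table3$events - mu)), 1e-6)
  expect_lt(abs(sum(table3$year * (table3$events - mu))), 1e-4)
  # cross-check against an independent direct likelihood maximisation
  # (year centred for numerical conditioning; the slope is unaffected)
  yc <- table3$year - mean(table3$year)
  nll <- function(b) -sum(stats::dpois(
    table3$events, exp(b[1] + b[2] * yc + log(table3$device_days)),
    log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(coef(fit)["slope"]), opt$par[2], tolerance = 1e-5)
})

test_that("trend needs three groups and positive exposures", {
  expect_error(poisson_trend(table3[1:2, ]), "at least 3")
  bad <- table3
  bad$device_days[1] <- 0
  expect_error(poisson_trend(bad), "positive")
})
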