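test_that("cleaned daily minimum removes artefacts then floors", {
  cfg <- surveillance_config()
  expect_equal(daily_min_respiratory(c(rep(0.40, 20), 0.21), "fio2", cfg),
               0.40)  # k = floor(1.05) = 1 removes the artefact
  cfg0 <- surveillance_config(low_outlier_fraction = 0)
  expect_equal(daily_min_respiratory(c(0.28, 0.35), "fio2", cfg0), 0.30)
  expect_true(is.na(daily_min_respiratory(numeric(0), "fio2", cfg)))
})

test_that("daily minimum equals the brute-force sort-slice-floor oracle", {
  set.seed(21)
  cfg_list <- list(surveillance_config(low_outlier_fraction = 0),
                   surveillance_config(low_outlier_fraction = 0.05),
                   surveillance_config(low_outlier_fraction = 0.2))
  for (i in 1:100) {
    n <- sample(1:50, 1)
    v <- round(runif(n, 0.15, 1), 2)
    for (cfg in cfg_list) {
      k <- floor(cfg$low_outlier_fraction * n)
      expected <- min(pmax(sort(v)[(k + 1):n], cfg$fio2_floor))
      expect_equal(daily_min_respiratory(v, "fio2", cfg), expected)
    }
  }
})

test_that("daily extremes pool sources after range filtering", {
  temps <- c(36.2, 38.4, 34.0)
  kept <- temps[filter_temperature(temps)]
  expect_equal(daily_extremes(kept), c(36.2, 38.4))
  expect_equal(daily_extremes(9.1), c(9.1, 9.1))
  expect_equal(daily_extremes(numeric(0)), c(NA_real_, NA_real_))
})

build_one <- function(measure_lines, ab_lines = character(),
                      config = surveillance_config()) {
  m <- read_measurements(write_measurements_csv(measure_lines), config)
  ab <- read_antimicrobials(write_antimicrobials_csv(ab_lines))
  ep <- vaesurv:::derive_all_episodes(m, config)
  build_daily_summaries(m, ep, ab, config)
}

test_that("summaries are gap-free with correct MV day numbering", {
  # etCO2 every 4 min across 4 days, temperature on days 1 and 6
  stamps <- format(seq(parse_timestamp("2010-01-01T08:00"),
                       parse_timestamp("2010-01-04T10:00"), by = 240),
                   "%Y-%m-%dT%H:%M")
  lines <- c(sprintf("A1,%s,etco2,35,", stamps),
             "A1,2010-01-01T09:00,temperature,37.0,tymp",
             "A1,2010-01-06T09:00,temperature,36.5,tymp")
  s <- build_one(lines)
  expect_equal(nrow(s), 6L)  # gap-free through the unventilated tail
  expect_equal(s$date, as.Date("2010-01-01") + 0:5)
  expect_equal(s$mv_day, c(1:4, NA, NA))
  expect_equal(s$ventilated, c(rep(TRUE, 4), FALSE, FALSE))
  expect_false(s$ventilated[6])
  expect_equal(s$min_temp[6], 36.5)
  expect_true(all(is.na(s$min_fio2)))
})

test_that("respiratory values outside ventilation episodes are ignored", {
  lines <- c("A1,2010-01-01T10:00,etco2,35,",
             "A1,2010-01-01T10:04,etco2,35,",
             "A1,2010-01-01T10:02,fio2,0.60,",
             "A1,2010-01-01T18:00,fio2,0.90,")  # after episode end
  s <- build_one(lines, config = surveillance_config(low_outlier_fraction = 0))
  expect_equal(s$min_fio2, 0.60)
})

test_that("new-agent starts use the two-day lookback", {
  lines <- c("A1,2010-01-01T10:00,etco2,35,",
             "A1,2010-01-08T10:00,temperature,37,")
  ab <- sprintf("A1,2010-01-%02d,vanco", 5:7)
  s <- build_one(lines, ab)
  expect_equal(s$new_agents[s$date == as.Date("2010-01-05")], "vanco")
  expect_equal(s$new_agents[s$date %in% (as.Date("2010-01-06") + 0:1)],
               c("", ""))
  # restart after a 2-day break counts as new again
  ab2 <- c(sprintf("A1,2010-01-%02d,vanco", c(1, 2)),
           sprintf("A1,2010-01-%02d,vanco", c(5, 6)))
  s2 <- build_one(lines, ab2)
  expect_equal(s2$new_agents[s2$date == as.Date("2010-01-05")], "vanco")
})

test_that("raising the exclusion fraction never lowers a daily minimum", {
  set.seed(31)
  stamps <- format(seq(parse_timestamp("2010-01-01T00:00"),
                       parse_timestamp("2010-01-03T23:59"), by = 600),
                   "%Y-%m-%dT%H:%M")
  vals <- round(runif(length(stamps), 0.2, 0.9), 2)
  lines <- c(sprintf("A1,%s,etco2,35,", stamps),
             sprintf("A1,%s,fio2,%.2f,", stamps, vals))
  s0 <- build_one(lines, config = surveillance_config(low_outlier_fraction = 0))
  s5 <- build_one(lines, config = surveillance_config(low_outlier_fraction = 0.05))
  expect_true(all(s5$min_fio2 >= s0$min_fio2, na.rm = TRUE))
})

test_that("cleaning report counts add up", {
  lines <- c("A1,2010-01-01T10:00,etco2,35,",
             "A1,2010-01-01T10:04,etco2,35,",
             "A1,2010-01-01T10:01,peep,3,",
             "A1,2010-01-01T10:03,peep,4,",
             "A1,2010-01-01T11:00,temperature,34.0,",
             "A1,2010-01-01T12:00,temperature,36.8,")
  s <- build_one(lines, config = surveillance_config(low_outlier_fraction = 0))
  rep <- cleaning_report(s)
  expect_equal(unname(rep["floored_peep_count"]), 2)
  expect_equal(unname(rep["excluded_temperature_count"]), 1)
  expect_equal(s$min_peep, 5)
  expect_equal(s$min_temp, 36.8)
})
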