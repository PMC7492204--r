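# Synthetic cohort generator: reproducibility, marginal calibration and
# the piecewise-exponential event process.

test_that("empty cohort and configuration validation", {
  expect_length(simulate_cohort(cohort_config(n_subjects = 0)), 0)
  expect_error(cohort_config(n_subjects = -1), "n_subjects")
  bad <- cohort_config()
  bad$relapse_count_dist$mono <- c(`1` = 0.7, `2` = 0.2)  # sums to 0.9
  expect_error(validate_cohort_config <- simulate_cohort(bad),
               "relapse_count_dist")
  bad2 <- cohort_config()
  bad2$edss_dist$mono <- c(`7.5` = 1)  # off the eligible grid
  expect_error(simulate_cohort(bad2), "edss_dist")
  expect_error(hazard_spec(rep(-0.1, 4), rep(0, 4)), "relapse_hazard")
  expect_error(hazard_spec(rep(0.1, 3), rep(0, 4)), "four pieces")
})

test_that("identical seed and config give a bit-identical cohort", {
  cfg <- cohort_config(n_subjects = 60, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(unclass(a), NULL), serialize(unclass(b), NULL))
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("patients.csv", "visits.csv", "relapses.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  c2 <- simulate_cohort(cohort_config(n_subjects = 60, seed = 124))
  expect_false(identical(serialize(unclass(a), NULL),
                         serialize(unclass(c2), NULL)))
})

test_that("female fraction lands within 3 binomial SDs of its target", {
  coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 2024))
  cv <- cohort_covariates(coh)
  p <- 0.75
  expect_lt(abs(mean(cv$sex == "female") - p), 3 * sqrt(p * (1 - p) / 300))
})

test_that("categorical marginals pass a goodness-of-fit check at n = 10000", {
  cfg <- cohort_config(n_subjects = 10000, seed = 31)
  coh <- simulate_cohort(cfg)
  cv <- cohort_covariates(coh)
  mono <- cv[cv$index_phenotype == "mono", ]
  checks <- list(
    list(x = mono$prior_dmt, p = cfg$dmt_dist$mono),
    list(x = mono$relapse_count_2y, p = cfg$relapse_count_dist$mono),
    list(x = mono$most_affected_kfs, p = cfg$most_affected_dist$mono),
    list(x = mono$dominant_symptom, p = cfg$dominant_symptom_dist$mono),
    list(x = mono$baseline_edss, p = cfg$edss_dist$mono))
  for (ch in checks) {
    obs <- table(factor(as.character(ch$x), levels = names(ch$p)))
    gof <- suppressWarnings(chisq.test(obs, p = ch$p))
    expect_gt(gof$p.value, 0.001)
  }
  # early-termination fraction near its 22.3% target
  drop_frac <- mean(!is.na(sapply(coh, function(r) r$termination_month)))
  expect_lt(abs(drop_frac - 0.223), 3 * sqrt(0.223 * 0.777 / 10000))
})

test_that("null event process produces no events", {
  hz <- hazard_spec(rep(0, 4), rep(0, 4), dropout_hazard = 0)
  ev <- simulate_event_times(hz, horizon = 24, seed = 1)
  expect_length(ev$relapse_times, 0)
  expect_true(is.na(ev$progression_time))
  expect_true(is.na(ev$dropout_time))
})

test_that("constant-hazard draws match the censored-exponential closed form", {
  h <- 0.05
  hz <- hazard_spec(rep(h, 4), rep(0, 4), dropout_hazard = 0)
  set.seed(99)
  draws <- replicate(10000, {
    ev <- simulate_event_times(hz, horizon = 24)
    if (length(ev$relapse_times)) ev$relapse_times[1] else NA_real_
  })
  p_event <- 1 - exp(-h * 24)
  frac <- mean(!is.na(draws))
  expect_lt(abs(frac - p_event), 3 * sqrt(p_event * (1 - p_event) / 10000))
  # censored-exponential mean among events: 1/h - 24 exp(-24h)/(1-exp(-24h))
  m_expected <- 1 / h - 24 * exp(-h * 24) / (1 - exp(-h * 24))
  expect_lt(abs(mean(draws, na.rm = TRUE) - m_expected), 0.4)
  # all times inside (0, horizon]
  expect_true(all(draws[!is.na(draws)] > 0 & draws[!is.na(draws)] <= 24))
})

test_that("a positive log hazard-ratio raises the event fraction (monotonicity)", {
  base <- hazard_spec(rep(0.02, 4), rep(0, 4),
                      log_hr = c(z = 0), dropout_hazard = 0)
  doubled <- hazard_spec(rep(0.02, 4), rep(0, 4),
                         log_hr = c(z = log(2)), dropout_hazard = 0)
  frac <- function(hz) {
    set.seed(7)
    mean(replicate(10000, length(simulate_event_times(
      hz, covariates = list(z = 1), horizon = 24)$relapse_times) > 0))
  }
  expect_gt(frac(doubled), frac(base))
})

test_that("piecewise hazards integrate correctly across segment boundaries", {
  # rate 0 on (0,6] and (12,18], rate r elsewhere: survival at 24 months
  # is exp(-12 r), and no event can fall in a zero-rate segment
  r <- 0.08
  hz <- hazard_spec(c(0, r, 0, r), rep(0, 4), dropout_hazard = 0)
  set.seed(123)
  draws <- replicate(5000, {
    ev <- simulate_event_times(hz, horizon = 24)
    if (length(ev$relapse_times)) ev$relapse_times[1] else NA_real_
  })
  p_event <- 1 - exp(-12 * r)
  expect_lt(abs(mean(!is.na(draws)) - p_event),
            3 * sqrt(p_event * (1 - p_event) / 5000))
  t <- draws[!is.na(draws)]
  expect_false(any(t <= 6 | (t > 12 & t <= 18)))
})

test_that("records are internally consistent", {
  coh <- simulate_cohort(cohort_config(n_subjects = 150, seed = 9))
  for (rec in coh) {
    expect_equal(rec$visits$month[1], 0)
    expect_false(is.unsorted(rec$visits$month, strictly = TRUE))
    expect_true(all(edss_on_grid <- abs(rec$visits$edss * 2 -
                                          round(rec$visits$edss * 2)) < 1e-9))
    expect_true(rec$index_relapse$onset_month < 0)
    expect_true(is_qualifying_relapse(rec$index_relapse))
    # every nominal visit that precedes termination is present within the
    # +/- 4 week window
    w <- 4 * 12 / 52
    for (nom in c(6, 12, 18, 24)) {
      if (is.na(rec$termination_month) || nom + w < rec$termination_month)
        expect_true(any(abs(rec$visits$month - nom) <= w + 1e-9),
                    label = sprintf("visit near month %d for %s", nom,
                                    rec$subject_id))
    }
    if (!is.na(rec$termination_month))
      expect_true(all(rec$visits$month <= rec$termination_month + 1e-9))
  }
})

test_that("Cox recovers a generated proportional effect from the cDAF endpoint", {
  cfg <- simulation_study_config(2000, seed = 4242,
                                 log_hr = c(poly = log(2)))
  d <- analysis_frame(simulate_cohort(cfg), "cDAF")
  f <- cox_fit(d, "poly")
  expect_gt(f$hr, 1.6)
  expect_lt(f$hr, 2.4)
  expect_true(f$ci95["poly", "low"] < 2 & 2 < f$ci95["poly", "high"])
})
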