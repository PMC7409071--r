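test_that("profiles enforce probabilistic and physical invariants", {
  p <- default_subject_profile("a", "patient", "robust", seed = 1)
  expect_s3_class(p, "subject_profile")
  expect_equal(rowSums(p$hmm_truth$transition), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p$hmm_truth$transition >= 0 & p$hmm_truth$transition <= 1))
  expect_gte(p$temp_truth$amp24, 0)
  expect_true(p$temp_truth$acro24 >= 0 && p$temp_truth$acro24 < 24)
  bad <- p$hmm_truth; bad$transition[1, 1] <- 0.5
  expect_error(subject_profile("b", p$group, p$phenotype, p$age, p$sex,
                               bad, p$temp_truth, p$cortisol_truth,
                               p$melatonin_truth, p$diary_truth, 0.5),
               "sum to 1")
})

test_that("disrupted defaults are weaker and less regular than robust", {
  for (i in 1:10) {
    r <- default_subject_profile("r", "patient", "robust", seed = 100 + i)
    d <- default_subject_profile("d", "patient", "disrupted", seed = 100 + i)
    expect_lt(d$hmm_truth$night_tilt, r$hmm_truth$night_tilt)
    expect_lt(d$temp_truth$amp24, r$temp_truth$amp24)
    expect_gt(d$diary_truth$retiring_sd, r$diary_truth$retiring_sd)
    expect_gt(d$diary_truth$rising_sd, r$diary_truth$rising_sd)
  }
})

test_that("generation is a pure function of profile and seed", {
  p <- default_subject_profile("a", "control", "robust", seed = 7)
  r1 <- generate_subject(p, days = 3)
  r2 <- generate_subject(p, days = 3)
  expect_identical(r1$activity$values, r2$activity$values)
  expect_identical(r1$temperature$values, r2$temperature$values)
  expect_identical(r1$melatonin$conc, r2$melatonin$conc)
  expect_identical(r1$diary$retiring, r2$diary$retiring)
})

test_that("generated records honour the measurement protocol", {
  p <- default_subject_profile("a", "patient", "robust", seed = 3)
  r <- generate_subject(p, days = 7)
  expect_equal(length(r$activity), 7 * 1440)
  expect_equal(length(r$temperature), length(r$activity))
  expect_equal(length(r$melatonin$conc), 6L)
  expect_equal(diff(as.numeric(r$melatonin$times)), rep(3600, 5))
  expect_equal(clock_hours(r$melatonin$times[1]), 19)
  expect_equal(length(r$cortisol$conc), 12L)
  expect_gte(length(r$cortisol$conc), 9L)   # panel adequacy by design
  expect_error(generate_subject(p, days = 2), "72-h")
  degen <- p; degen$hmm_truth$sdlog <- c(0, 0, 0)
  expect_error(generate_subject(degen, days = 7), "degenerate")
})

test_that("flat truth produces no dominant daily rhythm", {
  p <- default_subject_profile("flat", "control", "robust", seed = 5)
  p$hmm_truth$night_tilt <- 0
  p$hmm_truth$day_tilt <- 0
  p$diary_truth$retiring_sd <- 0
  p$diary_truth$rising_sd <- 0
  r <- generate_subject(p, days = 7)
  hourly <- aggregate_series(r$activity, 60, "mean")
  est <- dominant_rhythm(periodogram(interpolate_missing(hourly)),
                         n_resample = 50, n_scramble = 100, seed = 1)
  # no dominant daily peak: state persistence alone may put power at
  # arbitrary low frequencies, but never selectively at 24 h
  expect_false(est$significant && abs(est$dominant_period - 24) <= 1)
})

test_that("cohort generation matches requested composition with distinct seeds", {
  spec <- list(patients = c(disrupted = 2, robust = 2),
               controls = c(robust = 3))
  coh <- generate_cohort(spec, seed = 1, days = 3,
                         missing_events_per_day = 0)
  expect_length(coh$records, 7L)
  expect_equal(sum(coh$covariates$group == "patient"), 4L)
  expect_equal(sum(coh$covariates$phenotype == "disrupted"), 2L)
  seeds1 <- vapply(coh$records, function(r) r$truth$seed, numeric(1))
  coh2 <- generate_cohort(spec, seed = 2, days = 3,
                          missing_events_per_day = 0)
  seeds2 <- vapply(coh2$records, function(r) r$truth$seed, numeric(1))
  expect_length(intersect(seeds1, seeds2), 0L)
  expect_warning(generate_cohort(list(), seed = 1), "zero subjects")
  one <- generate_cohort(list(controls = c(robust = 1)), seed = 3,
                         days = 3, missing_events_per_day = 0)
  expect_length(one$records, 1L)
})

test_that("missingness injection is controlled and reversible to a truth mask", {
  p <- default_subject_profile("m", "control", "robust", seed = 11)
  r <- generate_subject(p, days = 7)
  r0 <- inject_missingness(r, 0)
  expect_identical(r0$activity$values, r$activity$values)
  r1 <- inject_missingness(r, 1)
  inj <- r1$injected_mask
  runs <- rle(inj)
  expect_equal(sum(runs$values), 7L)            # one span per day requested
  expect_true(all(runs$lengths[runs$values] >= 10 &
                    runs$lengths[runs$values] <= 40))
  expect_true(all(is.na(r1$activity$values[inj])))
  # injected temperature decays to room temperature
  expect_lt(min(r1$temperature$values[inj]), 23)
  expect_error(inject_missingness(r, 40), "50%")
})

test_that("phenotype defaults separate at the 97.5% threshold", {
  # reduced-size check of the frozen calibration property
  io <- sapply(c("robust", "disrupted"), function(ph) {
    vapply(1:15, function(i) {
      p <- default_subject_profile(ph, "patient", ph, seed = 5000 + i)
      r <- generate_subject(p, days = 3)
      beds <- bed_spans(r$diary, r$activity$start)
      compute_io(r$activity, beds)$io_percent
    }, numeric(1))
  })
  expect_gte(mean(io[, "robust"] > 97.5), 0.9)
  expect_gte(mean(io[, "disrupted"] <= 97.5), 0.9)
})
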