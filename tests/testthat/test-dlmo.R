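mk_mel <- function(conc, start_h = 19) {
  day <- as.POSIXct("2020-01-08 00:00:00", tz = "UTC")
  saliva_panel("melatonin", day + (start_h + seq_along(conc) - 1) * 3600,
               conc)
}

test_that("dim-light validity follows the 30-min pre-sample window", {
  dark <- light_series(t0(), rep(0, 1440))
  samples <- t0() + c(7, 8, 9) * 3600
  expect_equal(check_dim_light(dark, samples), rep(TRUE, 3))

  lux <- rep(0, 1440); lux[(7 * 60 + 31):(8 * 60)] <- 200
  bright <- light_series(t0(), lux)
  v <- check_dim_light(bright, samples)
  expect_equal(v, c(TRUE, FALSE, TRUE))

  # single-minute spike above 4x cutoff invalidates even with a low mean
  lux2 <- rep(0, 1440); lux2[8 * 60] <- 250
  expect_false(check_dim_light(light_series(t0(), lux2), samples)[2])

  # uncovered window is indeterminate
  short <- light_series(t0() + 7.9 * 3600, rep(0, 60))
  expect_true(is.na(check_dim_light(short, t0() + 7 * 3600)))
})

test_that("baseline thresholds follow the mean + 2 SD rule", {
  expect_equal(baseline_threshold(c(2, 2, 2)), 2)
  expect_equal(baseline_threshold(c(1, 2, 3)), 4)   # sample SD = 1

  flat <- mk_mel(c(2, 2, 2, 10, 20, 30))
  ind <- individual_threshold(flat)
  expect_equal(ind$threshold, 2)
  expect_equal(ind$run_start, 1L)

  steep <- mk_mel(c(2, 6, 14, 30, 50, 80))   # rising from the first sample
  expect_true(is.na(individual_threshold(steep)$threshold))
})

test_that("pooled thresholds aggregate group baselines", {
  p1 <- mk_mel(c(2, 2, 2, 10, 20, 30))
  p2 <- mk_mel(c(4, 4, 4, 12, 25, 40))
  pool <- pooled_threshold(list(p1, p2))
  expect_equal(pool$n_contributors, 2L)
  expect_equal(pool$threshold, 3 + 2 * sd(c(2, 2, 2, 4, 4, 4)),
               tolerance = 1e-12)
  expect_equal(pool$threshold, 5.19, tolerance = 1e-3)

  same <- pooled_threshold(list(mk_mel(c(3, 3, 3, 10, 20, 30)),
                                mk_mel(c(3, 3, 3, 12, 22, 33))))
  expect_equal(same$threshold, 3)
  expect_error(pooled_threshold(list(p1)), "at least 2")
})

test_that("the crossing time interpolates linearly and honours flags", {
  p <- saliva_panel("melatonin",
                    as.POSIXct("2020-01-08 21:00:00", tz = "UTC") +
                      c(0, 3600), c(3, 5))
  res <- compute_dlmo(p, 4)
  expect_true(res$determined)
  expect_equal(res$dlmo_clock_h, 21.5)

  low <- mk_mel(c(1, 1, 1, 2, 2, 2))
  expect_false(compute_dlmo(low, 10)$determined)
  expect_equal(compute_dlmo(low, 10)$flags, "never_exceeds_threshold")

  early <- mk_mel(c(9, 10, 12, 15, 20, 30))
  res <- compute_dlmo(early, 4)
  expect_false(res$determined)
  expect_equal(res$flags, "onset_precedes_window")

  # transient blips above threshold that fall back are not the onset
  blip <- mk_mel(c(2, 5, 2, 6, 8, 12))
  res <- compute_dlmo(blip, 4)
  expect_equal(res$dlmo_clock_h, clock_hours(blip$times[3]) +
                 (4 - 2) / (6 - 2), tolerance = 1e-9)
})

test_that("thresholds and onsets move monotonically", {
  p <- mk_mel(c(2, 2.1, 2, 6, 12, 25))
  d1 <- compute_dlmo(p, 3)
  d2 <- compute_dlmo(p, 5)
  expect_gte(d2$dlmo_clock_h, d1$dlmo_clock_h)
  # raising a baseline value never lowers the threshold
  expect_gte(baseline_threshold(c(2, 2.5, 3)), baseline_threshold(c(2, 2, 3)) - 1e-12)
  # unit equivariance: rescaling concentrations rescales thresholds,
  # leaves times unchanged
  p10 <- mk_mel(c(2, 2.1, 2, 6, 12, 25) * 10)
  t1 <- individual_threshold(p)$threshold
  t10 <- individual_threshold(p10)$threshold
  expect_equal(t10, 10 * t1, tolerance = 1e-12)
  expect_equal(compute_dlmo(p10, 10 * 3)$dlmo_clock_h, d1$dlmo_clock_h,
               tolerance = 1e-12)
})

test_that("synthetic logistic-rise truths are recovered near the onset", {
  err <- c()
  for (i in 1:20) {
    p <- default_subject_profile("d", "patient", "robust", seed = 800 + i)
    r <- generate_subject(p, days = 7)
    ind <- individual_threshold(r$melatonin)
    if (is.na(ind$threshold)) next
    d <- compute_dlmo(r$melatonin, ind$threshold)
    if (d$determined)
      err <- c(err, d$dlmo_clock_h - p$melatonin_truth$onset)
  }
  expect_gte(length(err), 5)
  expect_gte(mean(abs(err) <= 0.5), 0.8)
})
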