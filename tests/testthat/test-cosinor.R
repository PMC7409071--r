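test_that("noiseless two-harmonic temperature data are recovered exactly", {
  h <- clock_hours(mk_minutes(4))
  y <- two_harmonic_curve(h, 36.2, 0.3, -0.4, 0.1, 0.05)
  fit <- fit_temperature_cosinor(temperature_series(t0(), y),
                                 n_boot = 50, seed = 1)
  # the 1-h smoothing attenuates each harmonic by a known exact gain
  g1 <- ma_gain(24); g2 <- ma_gain(12)
  expect_equal(unname(fit$coef),
               c(36.2, 0.3 * g1, -0.4 * g1, 0.1 * g2, 0.05 * g2),
               tolerance = 1e-6)
  # acrophase is the argmax of the full fitted curve on a 1-min grid
  grid <- seq(0, 24 - 1 / 60, by = 1 / 60)
  expect_equal(fit$acrophase,
               grid[which.max(two_harmonic_curve(grid, 36.2, 0.3 * g1,
                                                 -0.4 * g1, 0.1 * g2,
                                                 0.05 * g2))],
               tolerance = 1e-6)
})

test_that("constant temperature fits a flat curve", {
  fit <- fit_temperature_cosinor(temperature_series(t0(), rep(36, 4 * 1440)),
                                 n_boot = 50, seed = 1)
  expect_equal(unname(fit$mesor), 36, tolerance = 1e-9)
  expect_lt(max(fit$amplitude), 1e-9)
})

test_that("profile coefficients equal the normal-equations solution", {
  set.seed(4)
  h <- clock_hours(mk_minutes(4))
  y <- 36 + rnorm(length(h), 0, 0.3)
  fit <- fit_temperature_cosinor(temperature_series(t0(), y),
                                 n_boot = 50, seed = 1)
  # independent route: brute-force centred moving average, averaged
  # profile, explicit normal-equations solve
  n <- length(y)
  sm <- vapply(seq_len(n), function(i) {
    if (i <= 30 || i > n - 30) return(NA_real_)   # full windows only
    mean(y[(i - 30):(i + 30)])
  }, numeric(1))
  prof <- tapply(sm, round(h * 60) %% 1440, mean, na.rm = TRUE)
  th <- as.numeric(names(prof)) / 60
  X <- cbind(1, sin(2 * pi * th / 24), cos(2 * pi * th / 24),
             sin(2 * pi * th / 12), cos(2 * pi * th / 12))
  keep <- !is.na(prof)
  beta <- solve(crossprod(X[keep, ]), crossprod(X[keep, ], prof[keep]))
  expect_equal(unname(fit$coef), as.numeric(beta), tolerance = 1e-6)
})

test_that("cortisol panel adequacy and exact recovery hold", {
  times <- t0() + (0:11) * 2 * 3600
  h <- clock_hours(times)
  y <- 10 + 5 * cos(2 * pi * (h - 8) / 24)
  short <- saliva_panel("cortisol", times[1:8], y[1:8])
  expect_error(fit_cortisol_cosinor(short), "inadequate")

  fit <- fit_cortisol_cosinor(saliva_panel("cortisol", times, y),
                              n_boot = 50, seed = 1)
  expect_equal(unname(fit$mesor), 10, tolerance = 1e-8)
  expect_equal(unname(fit$amplitude[1]), 5, tolerance = 1e-8)
  expect_equal(fit$acrophase, 8, tolerance = 1 / 60 + 1e-9)
  expect_true(fit$significant)
})

test_that("single-harmonic fit nests inside the two-harmonic model", {
  h <- clock_hours(mk_minutes(4))
  y <- two_harmonic_curve(h, 36, 0.25, -0.35, 0, 0)
  fit2 <- fit_temperature_cosinor(temperature_series(t0(), y),
                                  n_boot = 50, seed = 1)
  expect_lt(fit2$amplitude[["h12"]], 1e-6)
  times <- t0() + (0:95) * 900
  hh <- clock_hours(times)
  p <- saliva_panel("cortisol", times,
                    two_harmonic_curve(hh, 36, 0.25, -0.35, 0, 0))
  fit1 <- fit_cortisol_cosinor(p, n_boot = 50, seed = 1)
  # the raw-time fit sees the unsmoothed amplitude
  expect_equal(unname(fit1$amplitude[1]) * ma_gain(24),
               unname(fit2$amplitude[["h24"]]), tolerance = 1e-6)
  expect_equal(fit1$acrophase, fit2$acrophase, tolerance = 1 / 30)
})

test_that("fits are invariant to the time origin up to phase", {
  h <- clock_hours(mk_minutes(4))
  y <- two_harmonic_curve(h, 36.2, 0.3, -0.4, 0.1, 0.05)
  f1 <- fit_temperature_cosinor(temperature_series(t0(), y), 50, 1)
  f2 <- fit_temperature_cosinor(temperature_series(t0() + 6 * 3600, y),
                                50, 1)
  expect_equal(unname(f1$amplitude), unname(f2$amplitude),
               tolerance = 1e-6)
  expect_equal((f2$acrophase - f1$acrophase) %% 24, 6, tolerance = 1e-3)
})

test_that("temperature rhythms classify by period, phase and significance", {
  sig24 <- list(significant = TRUE, dominant_period = 24)
  expect_equal(classify_temperature_rhythm(sig24, list(acrophase = 2))$label,
               "physiologic")
  expect_equal(classify_temperature_rhythm(sig24, list(acrophase = 14))$label,
               "abnormal")
  expect_equal(classify_temperature_rhythm(
    list(significant = FALSE, dominant_period = 24),
    list(acrophase = 2))$label, "arrhythmic")
  # closed nocturnal boundaries 22:01 and 07:00
  expect_equal(classify_temperature_rhythm(
    sig24, list(acrophase = 22 + 1 / 60))$label, "physiologic")
  expect_equal(classify_temperature_rhythm(
    sig24, list(acrophase = 7))$label, "physiologic")
  expect_equal(classify_temperature_rhythm(
    list(significant = TRUE, dominant_period = 20),
    list(acrophase = 2))$label, "abnormal")
})
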