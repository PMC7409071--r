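test_that("sensor CSVs parse with grid completion and strict ordering", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "a.csv")
  ts <- format(t0() + c(0, 60, 120), "%Y-%m-%dT%H:%M:%S")
  write.csv(data.frame(timestamp = ts, value = c(1, 2, 3)), f,
            row.names = FALSE)
  s <- read_series(f, "activity")
  expect_equal(s$values, c(1, 2, 3))
  expect_false(any(s$missing))

  write.csv(data.frame(timestamp = ts[c(1, 3)], value = c(1, 3)), f,
            row.names = FALSE)
  s <- read_series(f, "activity")
  expect_equal(length(s), 3L)
  expect_true(s$missing[2])

  write.csv(data.frame(timestamp = ts[c(1, 3, 2)], value = 1:3), f,
            row.names = FALSE)
  expect_error(read_series(f, "activity"), "non-monotone.*row 3")
  write.csv(data.frame(timestamp = ts[c(1, 1, 2)], value = 1:3), f,
            row.names = FALSE)
  expect_error(read_series(f, "activity"), "duplicate")
})

test_that("a written subject directory reads back equal", {
  p <- default_subject_profile("rt", "control", "robust", seed = 21)
  r <- generate_subject(p, days = 3)
  dir <- withr::local_tempdir()
  write_subject_dir(r, dir)
  back <- read_subject_dir(dir)
  expect_equal(back$activity$values, r$activity$values)
  expect_equal(back$temperature$values, r$temperature$values,
               tolerance = 1e-12)
  expect_equal(back$activity$start, r$activity$start)
  expect_equal(back$melatonin$conc, r$melatonin$conc, tolerance = 1e-12)
  expect_equal(back$diary$retiring, r$diary$retiring, tolerance = 1e-3)
})

test_that("off-body spans are recovered with few false positives", {
  ok <- temperature_series(t0(), rep(35, 2000))
  act <- activity_series(t0(), rep(10, 2000))
  sp <- detect_missing_spans(ok, act)
  expect_false(any(sp$mask))

  # decay only down to 30 C never triggers the room-temperature rule
  v <- rep(35, 2000); v[500:540] <- seq(35, 30, length.out = 41)
  sp <- detect_missing_spans(temperature_series(t0(), v), act)
  expect_false(any(sp$mask))

  rec <- vapply(1:10, function(i) {
    p <- default_subject_profile("s", "control", "robust", seed = 600 + i)
    r <- generate_subject(p, days = 7)
    r <- inject_missingness(r, 1)
    sp <- detect_missing_spans(r$temperature, r$activity)
    c(sum(sp$mask & r$injected_mask) / sum(r$injected_mask),
      sum(sp$mask & !r$injected_mask) / sum(!r$injected_mask))
  }, numeric(2))
  expect_true(all(rec[1, ] >= 0.9))
  expect_true(all(rec[2, ] < 0.02))

  expect_error(
    detect_missing_spans(temperature_series(t0(), rep(NA_real_, 10)),
                         activity_series(t0(), rep(NA_real_, 10))),
    "no analyzable data")
})

test_that("a span at the series start is caught by the plateau rule alone", {
  p <- default_subject_profile("e", "control", "robust", seed = 9)
  r <- generate_subject(p, days = 3)
  r <- inject_missingness(r, 0, spans = matrix(c(1, 20), 1))
  sp <- detect_missing_spans(r$temperature, r$activity)
  expect_gte(sum(sp$mask[1:20]) / 20, 0.9)
})

test_that("aggregation applies the bin completeness rule and matches brute force", {
  s <- activity_series(t0(), rep(10, 120))
  b <- aggregate_series(s, 5, "mean")
  expect_equal(b$values, rep(10, 24))

  v <- rep(1, 60); v[6:60] <- NA   # 5 present + 55 missing in the hour
  b <- aggregate_series(activity_series(t0(), v), 60, "mean")
  expect_true(b$missing[1])

  set.seed(1)
  v <- rpois(180, 20); v[sample(180, 30)] <- NA
  s <- activity_series(t0(), v)
  b <- aggregate_series(s, 60, "mean")
  for (k in 1:3) {
    chunk <- v[(k - 1) * 60 + 1:60]
    if (mean(is.na(chunk)) > 0.5) expect_true(b$missing[k])
    else expect_equal(b$values[k], mean(chunk, na.rm = TRUE))
  }
  expect_error(aggregate_series(b, 30), "finer")
  expect_error(aggregate_series(s, 7), "divide evenly")
})

test_that("interpolation is linear, convex and better than zero-fill", {
  b <- structure(list(kind = "activity", start = t0(), step = 3600,
                      values = c(1, NA, 3), missing = c(FALSE, TRUE, FALSE)),
                 class = "binned_series")
  expect_warning(out <- interpolate_missing(b), "interpolated")
  expect_equal(out$values, c(1, 2, 3))
  expect_equal(attr(out, "fraction_interpolated"), 1 / 3, tolerance = 1e-12)

  full <- structure(list(kind = "activity", start = t0(), step = 3600,
                         values = 1:5, missing = rep(FALSE, 5)),
                    class = "binned_series")
  expect_equal(interpolate_missing(full)$values, as.numeric(1:5))

  set.seed(2)
  sin5 <- mk_sinusoid(5, 24, 10, 3, mesor = 20)
  truth <- sin5$values
  gap <- sample(length(truth), 12)
  sin5$values[gap] <- NA; sin5$missing[gap] <- TRUE
  out <- interpolate_missing(sin5)
  rmse_lin <- sqrt(mean((out$values[gap] - truth[gap])^2))
  rmse_zero <- sqrt(mean((0 - truth[gap])^2))
  expect_lt(rmse_lin, rmse_zero)
  # interpolated values stay inside the hull of their neighbours
  expect_true(all(out$values >= min(truth) & out$values <= max(truth)))
})
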