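# brute-force reference: literal minute-by-minute scan
io_brute <- function(activity, beds, window) {
  times <- series_times(activity)
  n_in <- 0; n_below <- 0; out_vals <- c()
  inb <- rep(FALSE, length(times))
  for (i in seq_len(nrow(beds)))
    inb <- inb | (times >= beds$bed_start[i] & times < beds$bed_end[i])
  sel <- times >= window[1] & times < window[2] & !activity$missing
  for (j in which(sel & !inb)) out_vals <- c(out_vals, activity$values[j])
  med <- median(out_vals)
  for (j in which(sel & inb)) {
    n_in <- n_in + 1
    if (activity$values[j] < med) n_below <- n_below + 1
  }
  100 * n_below / n_in
}

test_that("dichotomy index handles the strict-inequality boundary", {
  # one day: in bed 23:00-07:00 with zeros, awake with 10/20/30/40 pattern
  d <- mk_diary(1)
  beds <- bed_spans(d, t0())
  counts <- rep(c(10, 20, 30, 40), length.out = 1440)
  times <- mk_minutes(1)
  inb <- times >= beds$bed_start[1] & times < beds$bed_end[1]
  counts[inb] <- 0
  io <- compute_io(mk_activity(counts), beds)
  expect_equal(io$io_percent, 100)
  expect_equal(io$out_median, 25)

  counts[inb] <- 25                     # ties with the median count as not below
  io <- compute_io(mk_activity(counts), beds)
  expect_equal(io$io_percent, 0)
})

test_that("compute_io equals the brute-force minute scan", {
  for (i in 1:3) {
    p <- default_subject_profile("b", "patient",
                                 c("robust", "disrupted")[1 + i %% 2],
                                 seed = 300 + i)
    r <- generate_subject(p, days = 7)
    beds <- bed_spans(r$diary, r$activity$start)
    w <- c(r$activity$start, r$activity$start + 7 * 86400)
    io <- compute_io(r$activity, beds, w)
    expect_equal(io$io_percent, io_brute(r$activity, beds, w),
                 tolerance = 1e-12)
  }
})

test_that("index is scale invariant and monotone in in-bed activity", {
  p <- default_subject_profile("s", "patient", "disrupted", seed = 77)
  r <- generate_subject(p, days = 3)
  beds <- bed_spans(r$diary, r$activity$start)
  base <- compute_io(r$activity, beds)$io_percent
  scaled <- r$activity
  scaled$values <- scaled$values * 3.7
  expect_equal(compute_io(scaled, beds)$io_percent, base,
               tolerance = 1e-12)
  times <- series_times(r$activity)
  inb <- rep(FALSE, length(times))
  for (i in seq_len(nrow(beds)))
    inb <- inb | (times >= beds$bed_start[i] & times < beds$bed_end[i])
  bumped <- r$activity
  bumped$values[inb] <- bumped$values[inb] + 15
  expect_lte(compute_io(bumped, beds)$io_percent, base)
})

test_that("the 72-h window nests inside the full series", {
  p <- default_subject_profile("n", "control", "robust", seed = 88)
  r <- generate_subject(p, days = 7)
  beds <- bed_spans(r$diary, r$activity$start)
  w72 <- c(r$activity$start, r$activity$start + 72 * 3600)
  io_a <- compute_io(r$activity, beds, w72)
  first72 <- activity_series(r$activity$start,
                             r$activity$values[1:(72 * 60)])
  io_b <- compute_io(first72, beds)
  expect_equal(io_a$io_percent, io_b$io_percent, tolerance = 1e-12)
  expect_equal(io_a$category, io_b$category)
})

test_that("classification applies the 97.5% boundary inclusively", {
  expect_equal(classify_io(90.4), "low")
  expect_equal(classify_io(98.7), "high")
  expect_equal(classify_io(97.5), "low")
  expect_error(classify_io(101), "\\[0, 100\\]")
})

test_that("degenerate and missing rest inputs are rejected or flagged", {
  d <- mk_diary(1)
  beds <- bed_spans(d, t0())
  a <- mk_activity(rep(0, 1440))
  io <- compute_io(a, beds)
  expect_equal(io$io_percent, 0)
  expect_true(io$degenerate_out_median)
  late <- bed_spans(mk_diary(1), t0() + 10 * 86400)
  expect_error(compute_io(a, late), "rest interval")
})
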