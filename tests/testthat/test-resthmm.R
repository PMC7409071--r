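test_that("simulated truths are recovered by EM", {
  truth <- example_hmm_truth()
  ok <- vapply(1:5, function(i) {
    sim <- simulate_hmm_bins(truth, 2016, seed = 100 + i)
    m <- fit_hmm(sim$counts, seed = i)
    m$n_states == 3 &&
      all(abs(m$transition - truth$transition) <= 0.05) &&
      all(abs(m$mu - truth$mu) / truth$mu <= 0.10)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("fits are deterministic and ordered, with monotone likelihood", {
  sim <- simulate_hmm_bins(example_hmm_truth(), 864, seed = 4)
  m1 <- fit_hmm(sim$counts, seed = 9)
  m2 <- fit_hmm(sim$counts, seed = 9)
  expect_identical(m1$mu, m2$mu)
  expect_identical(m1$transition, m2$transition)
  expect_true(all(diff(m1$mu) > 0))
  expect_equal(rowSums(m1$transition), rep(1, 3), tolerance = 1e-9)
  expect_true(all(diff(m1$ll_trace) > -1e-8))
})

test_that("structureless input falls back to a flagged 2-state fit", {
  m <- fit_hmm(rep(0, 600), seed = 1)
  expect_true(m$degenerate)
  expect_equal(m$n_states, 2L)
  expect_error(fit_hmm(rep(1, 100), seed = 1), "288")
})

test_that("decoding matches a threshold oracle for separated emissions", {
  truth <- list(mu = log(c(0, 50, 500) + 1), sigma = c(0.3, 0.3, 0.3),
                transition = example_hmm_truth()$transition)
  sim <- simulate_hmm_bins(truth, 2016, seed = 5)
  m <- fit_hmm(sim$counts, seed = 2)
  dec <- decode_states(m, sim$counts)
  y <- log(sim$counts + 1)
  cuts <- c(mean(m$mu[1:2]), mean(m$mu[2:3]))
  oracle <- 1L + (y > cuts[1]) + (y > cuts[2])
  expect_gte(mean(dec$path == oracle), 0.99)
  expect_equal(rowSums(dec$posteriors), rep(1, 2016), tolerance = 1e-9)
})

test_that("a single bin decodes by stationary-weighted emission likelihood", {
  m <- mk_model(mu = c(0, 4, 6))
  dec <- decode_states(m, 55)   # log(56) ~ 4.02, nearest MA
  expect_equal(dec$path, 2L)
  expect_equal(sum(dec$posteriors), 1, tolerance = 1e-9)
})

test_that("P1-1 tracks the empirical rest-persistence frequency", {
  truth <- example_hmm_truth()
  sim <- simulate_hmm_bins(truth, 1e5, seed = 6)
  m <- fit_hmm(sim$counts, seed = 3, n_restarts = 2)
  s <- sim$states
  emp <- sum(s[-length(s)] == 1 & s[-1] == 1) / sum(s[-length(s)] == 1)
  expect_lt(abs(m$transition[1, 1] - emp), 0.02)
})

test_that("rhythm index spans its endpoints", {
  path <- mk_block_path(4, 23, 7)
  d <- derive_metrics(mk_model(), mk_decoding(path))
  expect_equal(d$ri, 1.0)
  expect_equal(d$center_of_rest, 3, tolerance = 0.05)

  set.seed(8)
  null_ri <- vapply(1:200, function(i) {
    derive_metrics(mk_model(), mk_decoding(sample(path)))$ri
  }, numeric(1))
  # a structured path is far outside the shuffled null; shuffled paths
  # are mutually indistinguishable
  expect_gt(d$ri, quantile(null_ri, 0.95))
  expect_lt(median(null_ri), 0.5)
})

test_that("no-rest paths report undefined rest metrics", {
  path <- rep(2L, 600)
  d <- derive_metrics(mk_model(), mk_decoding(path))
  expect_true(is.na(d$ri))
  expect_true(is.na(d$center_of_rest))
})

test_that("sleep windows and their variability follow the decoded path", {
  path <- mk_block_path(4, 23, 7)
  sw <- estimate_sleep_windows(mk_decoding(path))
  expect_equal(nrow(sw$windows), 4L)
  expect_equal(sw$sleep_duration_sd, 0)
  expect_equal(sw$windows$duration_h, rep(8, 4), tolerance = 1e-9)

  # durations 7, 8, 9 h -> sample SD 1 h
  p7 <- mk_block_path(1, 23, 6)
  p8 <- mk_block_path(1, 23, 7)
  p9 <- mk_block_path(1, 23, 8)
  path <- c(p7, p8, p9)
  sw <- estimate_sleep_windows(mk_decoding(path))
  expect_equal(sort(sw$windows$duration_h), c(7, 8, 9), tolerance = 1e-9)
  expect_equal(sw$sleep_duration_sd, 1, tolerance = 1e-9)

  # a day with no nocturnal rest is skipped and counted
  path <- c(mk_block_path(2, 23, 7), rep(2L, 288), mk_block_path(1, 23, 7))
  sw <- estimate_sleep_windows(mk_decoding(path))
  expect_equal(sw$days_without_rest, 1L)
  expect_error(estimate_sleep_windows(mk_decoding(mk_block_path(2))),
               "3 study days")
})

test_that("decoded sleep onsets track the diary truth", {
  hits <- n <- 0
  for (i in 1:3) {
    p <- default_subject_profile("sw", "control", "robust", seed = 700 + i)
    r <- generate_subject(p, days = 7)
    act5 <- aggregate_series(r$activity, 5, "mean")
    m <- fit_hmm(act5, seed = i)
    dec <- decode_states(m, act5)
    sw <- estimate_sleep_windows(dec)
    beds <- bed_spans(r$diary, r$activity$start)
    j <- match(sw$windows$day, beds$day)
    err_h <- abs(as.numeric(difftime(sw$windows$onset, beds$bed_start[j],
                                     units = "hours")))
    hits <- hits + sum(err_h <= 0.5)
    n <- n + length(err_h)
  }
  expect_gte(hits / n, 0.8)
})

test_that("harmonic transitions stay stochastic around the clock", {
  p <- default_subject_profile("h", "patient", "robust", seed = 31)
  r <- generate_subject(p, days = 7)
  act5 <- aggregate_series(r$activity, 5, "mean")
  m <- fit_hmm(act5, harmonic = TRUE, seed = 1, n_restarts = 2,
               max_iter = 100)
  for (mat in transition_at(m, c(0, 3.7, 12, 18.25, 23.9))) {
    expect_equal(unname(rowSums(mat)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(mat >= 0))
  }
  dec <- decode_states(m, act5)
  d <- derive_metrics(m, dec)
  # time-averaged and matrix-level rest persistence are both reported
  expect_true(d$p11 >= 0 && d$p11 <= 1)
  expect_true(d$p11_matrix >= 0 && d$p11_matrix <= 1)
})
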