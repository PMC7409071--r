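# shared fixture builders (all generated in code)

t0 <- function() as.POSIXct("2020-01-06 12:00:00", tz = "UTC")

# activity series from a per-minute count vector
mk_activity <- function(counts, start = t0()) {
  activity_series(start, counts)
}

# n days of minute timestamps
mk_minutes <- function(days, start = t0()) {
  start + (seq_len(days * 1440) - 1) * 60
}

# simple one-interval-per-day diary: retiring 23:00, rising 07:00
mk_diary <- function(days, retiring = 23, rising = 7) {
  diary_log(seq_len(days), rep(retiring, days), rep(rising, days))
}

# pure sinusoid sampled hourly: period in h, amplitude, clock acrophase
mk_sinusoid <- function(days, period = 24, amplitude = 1, acrophase = 2,
                        mesor = 0, start = t0()) {
  n <- days * 24
  times <- start + (seq_len(n) - 1) * 3600
  h_abs <- as.numeric(difftime(times, start, units = "hours")) +
    clock_hours(start)
  structure(list(kind = "activity", start = start, step = 3600,
                 values = mesor + amplitude *
                   cos(2 * pi * (h_abs - acrophase) / period),
                 missing = rep(FALSE, n)),
            class = "binned_series")
}

two_harmonic_curve <- function(h, M, a1, b1, a2, b2) {
  M + a1 * sin(2 * pi * h / 24) + b1 * cos(2 * pi * h / 24) +
    a2 * sin(2 * pi * h / 12) + b2 * cos(2 * pi * h / 12)
}

# exact gain of the centred 61-min moving average on a T-hour harmonic
ma_gain <- function(period_h) {
  w <- 2 * pi / (60 * period_h)
  sin(61 * w / 2) / (61 * sin(w / 2))
}

# fake fitted model for metric tests that bypass EM
mk_model <- function(mu = c(0, 4, 6), transition = NULL) {
  K <- length(mu)
  if (is.null(transition)) {
    transition <- matrix(0.05 / (K - 1), K, K); diag(transition) <- 0.95
  }
  structure(list(n_states = K, labels = c("IA", "MA", "HA")[1:K],
                 mu = mu, sigma = rep(0.3, K), transition = transition,
                 init = rep(1 / K, K), harmonic = NULL, loglik = 0,
                 converged = TRUE, bin_min = 5, start = t0(),
                 n_bins = NA_integer_),
            class = "hmm_model")
}

# decoding object from an explicit path (posterior 1 on the decoded state)
mk_decoding <- function(path, bin_min = 5, start = t0(), K = 3) {
  n <- length(path)
  post <- matrix(0, n, K)
  post[cbind(seq_len(n), path)] <- 1
  structure(list(path = as.integer(path), posteriors = post,
                 times = start + (seq_len(n) - 1) * bin_min * 60,
                 missing = rep(FALSE, n), counts = rep(0, n), loglik = 0),
            class = "hmm_decoding")
}

# daily rest block path: IA during [block_start, block_end) clock hours
mk_block_path <- function(days, block_start = 23, block_end = 7,
                          bin_min = 5, start = t0()) {
  n <- days * 24 * 60 / bin_min
  times <- start + (seq_len(n) - 1) * bin_min * 60
  h <- clock_hours(times)
  in_block <- if (block_start > block_end)
    h >= block_start | h < block_end else h >= block_start & h < block_end
  ifelse(in_block, 1L, 2L)
}
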