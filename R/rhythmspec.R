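# Least-squares spectral rhythm estimation on hourly aggregated series:
# dominant period, amplitude and acrophase with resampling confidence
# intervals, a phase-scrambling significance test, and the 24-h
# autocorrelation r24.

as_hourly <- function(x) {
  if (is.numeric(x))
    return(list(y = x, t_h = seq_along(x) - 1, clock0 = 0))
  stopifnot(inherits(x, "binned_series"))
  list(y = x$values, t_h = (seq_along(x$values) - 1) * x$step / 3600,
       clock0 = clock_hours(x$start))
}

# QR factors of the sinusoid design at each grid period (reused across
# resamples and scrambles)
spectrum_designs <- function(t_h, period_grid) {
  lapply(period_grid, function(p) {
    X <- cbind(1, sin(2 * pi * t_h / p), cos(2 * pi * t_h / p))
    qr.Q(qr(X))
  })
}

# variance-explained spectrum for each column of Y (T x R matrix)
spectrum_matrix <- function(Y, Qs) {
  Y <- as.matrix(Y)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  out <- matrix(0, length(Qs), ncol(Y))
  for (i in seq_along(Qs)) {
    Q <- Qs[[i]]
    F <- Q %*% crossprod(Q, Y)
    out[i, ] <- 1 - colSums((Y - F)^2) / pmax(tss, 1e-300)
  }
  # a constant column explains no variance at any period
  out[, tss < 1e-12] <- 0
  out
}

sin_fit <- function(y, t_h, p) {
  X <- cbind(1, sin(2 * pi * t_h / p), cos(2 * pi * t_h / p))
  cf <- qr.coef(qr(X), y)
  list(coef = cf, fitted = as.numeric(X %*% cf),
       amplitude = sqrt(cf[2]^2 + cf[3]^2),
       peak_rel_h = (atan2(cf[2], cf[3]) / (2 * pi) * p) %% p)
}

#' Least-squares periodogram
#'
#' For each candidate period a sinusoid (plus intercept) is fitted by
#' least squares to the complete (interpolated) hourly series; the
#' spectrum value is the variance explained. The per-period amplitude and
#' acrophase (clock time of the fitted maximum) are retained.
#'
#' @param hourly a complete hourly `binned_series` (after
#'   [interpolate_missing()]) or a plain numeric vector.
#' @param period_grid candidate periods in hours.
#' @return A `periodogram` data-frame-like list with `period`, `power`
#'   (R^2), `amplitude`, `acrophase`, plus the input kept for resampling.
#' @export
periodogram <- function(hourly, period_grid = seq(6, 30, by = 0.1)) {
  dat <- as_hourly(hourly)
  if (anyNA(dat$y)) stop("periodogram requires a complete series")
  span_h <- max(dat$t_h) - min(dat$t_h)
  if (span_h < 2 * max(period_grid))
    stop("series must cover at least twice the longest candidate period")
  if (span_h < 72) stop("need at least 72 h of data")
  Qs <- spectrum_designs(dat$t_h, period_grid)
  power <- as.numeric(spectrum_matrix(dat$y, Qs))
  amp <- numeric(length(period_grid)); acro <- numeric(length(period_grid))
  for (i in seq_along(period_grid)) {
    f <- sin_fit(dat$y, dat$t_h, period_grid[i])
    amp[i] <- f$amplitude
    acro[i] <- (dat$clock0 + f$peak_rel_h) %% 24
  }
  structure(list(period = period_grid, power = power, amplitude = amp,
                 acrophase = acro, y = dat$y, t_h = dat$t_h,
                 clock0 = dat$clock0, designs = Qs),
            class = "periodogram")
}

# Scrambled surrogate for the no-rhythm null: a random permutation of the
# series, which keeps the marginal distribution but destroys all temporal
# structure. (Fourier phase randomization is unsuitable here: it preserves
# the power spectrum, and with it the very peak being tested.)
scramble_series <- function(y) sample(y)

#' Dominant rhythm with resampling confidence intervals
#'
#' The dominant period is the spectrum argmax (ties resolved towards the
#' smaller period). 90% confidence intervals for period, amplitude and
#' acrophase come from residual resampling of the dominant-period fit with
#' re-estimation over the full grid; significance compares the observed
#' peak against the 95th percentile of the peak heights of scrambled
#' surrogates.
#'
#' @param spec a [periodogram()] result.
#' @param n_resample residual-bootstrap resamples for the CIs.
#' @param n_scramble phase-scrambled surrogates for the null.
#' @param seed integer seed.
#' @param ci_level confidence level (default 0.90).
#' @return A `rhythm_estimate`: `dominant_period`, `amplitude`,
#'   `acrophase`, `ci90_period`, `ci90_amplitude`, `ci90_acrophase`,
#'   `significant`, `null_cutoff`.
#' @export
dominant_rhythm <- function(spec, n_resample = 500L, n_scramble = 200L,
                            seed = 1L, ci_level = 0.90) {
  stopifnot(inherits(spec, "periodogram"))
  i_max <- which(spec$power == max(spec$power))
  if (length(i_max) > 1) {
    message("spectrum tie at the maximum; smaller period retained")
    i_max <- min(i_max)
  }
  p_hat <- spec$period[i_max]
  fit <- sin_fit(spec$y, spec$t_h, p_hat)
  a_hat <- fit$amplitude
  phi_hat <- (spec$clock0 + fit$peak_rel_h) %% 24
  res <- spec$y - fit$fitted
  alpha <- (1 - ci_level) / 2

  with_seed(seed, {
    n <- length(spec$y)
    Yb <- matrix(sample(res, n * n_resample, replace = TRUE), n) + fit$fitted
    pw <- spectrum_matrix(Yb, spec$designs)
    ib <- apply(pw, 2, which.max)
    pb <- spec$period[ib]
    ab <- numeric(n_resample); phb <- numeric(n_resample)
    for (r in seq_len(n_resample)) {
      f <- sin_fit(Yb[, r], spec$t_h, pb[r])
      ab[r] <- f$amplitude
      phb[r] <- (spec$clock0 + f$peak_rel_h) %% 24
    }
    # centre acrophase differences on the estimate before taking quantiles
    dphi <- ((phb - phi_hat + 12) %% 24) - 12
    ci_phi <- (phi_hat + stats::quantile(dphi, c(alpha, 1 - alpha),
                                         names = FALSE)) %% 24
    Ys <- vapply(seq_len(n_scramble), function(i) scramble_series(spec$y),
                 numeric(n))
    null_max <- apply(spectrum_matrix(Ys, spec$designs), 2, max)
    cutoff <- stats::quantile(null_max, 0.95, names = FALSE)
    structure(list(
      dominant_period = p_hat, amplitude = a_hat, acrophase = phi_hat,
      ci90_period = stats::quantile(pb, c(alpha, 1 - alpha), names = FALSE),
      ci90_amplitude = stats::quantile(ab, c(alpha, 1 - alpha),
                                       names = FALSE),
      ci90_acrophase = ci_phi,
      significant = max(spec$power) > cutoff,
      null_cutoff = cutoff, peak_power = max(spec$power)),
      class = "rhythm_estimate")
  })
}

#' 24-hour autocorrelation r24
#'
#' Pearson correlation of the hourly series with itself shifted by 24 h;
#' pairs with a missing member are dropped.
#'
#' @param hourly an hourly `binned_series` (missing values allowed) or
#'   numeric vector.
#' @return list with `r24` (`NA` when variance is zero, with
#'   `undefined = TRUE`) and `n_pairs`.
#' @export
autocorr24 <- function(hourly) {
  dat <- as_hourly(hourly)
  step_h <- if (length(dat$t_h) > 1) dat$t_h[2] - dat$t_h[1] else 1
  lag <- as.integer(round(24 / step_h))
  n <- length(dat$y)
  if (n <= lag + 1) stop("need at least 48 h of data")
  x <- dat$y[seq_len(n - lag)]
  z <- dat$y[seq_len(n - lag) + lag]
  ok <- !is.na(x) & !is.na(z)
  x <- x[ok]; z <- z[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(z) == 0)
    return(list(r24 = NA_real_, n_pairs = length(x), undefined = TRUE))
  list(r24 = stats::cor(x, z), n_pairs = length(x), undefined = FALSE)
}
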