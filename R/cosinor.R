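# Cosinor rhythm models: two-harmonic (24 h + 12 h) fit to the averaged
# daily chest temperature profile, single-harmonic 24-h fit to raw-time
# cortisol samples; bootstrap confidence intervals and the
# physiologic / abnormal / arrhythmic temperature classification.

cosinor_design <- function(t_h, two_harmonic = FALSE) {
  X <- cbind(1, sin(2 * pi * t_h / 24), cos(2 * pi * t_h / 24))
  if (two_harmonic)
    X <- cbind(X, sin(2 * pi * t_h / 12), cos(2 * pi * t_h / 12))
  X
}

# evaluate a fitted cosinor curve on a clock grid and locate its maximum
cosinor_acrophase <- function(cf, two_harmonic) {
  grid <- seq(0, 24 - 1 / 60, by = 1 / 60)
  yy <- as.numeric(cosinor_design(grid, two_harmonic) %*% cf)
  grid[which.max(yy)]
}

fit_cosinor_core <- function(t_h, y, two_harmonic) {
  X <- cosinor_design(t_h, two_harmonic)
  cf <- qr.coef(qr(X), y)
  amp <- c(h24 = sqrt(cf[2]^2 + cf[3]^2))
  if (two_harmonic) amp <- c(amp, h12 = sqrt(cf[4]^2 + cf[5]^2))
  list(coef = cf, mesor = cf[1], amplitude = amp,
       acrophase = cosinor_acrophase(cf, two_harmonic),
       fitted = as.numeric(X %*% cf))
}

wrap_ci <- function(boot_vals, center, alpha) {
  d <- ((boot_vals - center + 12) %% 24) - 12
  (center + stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)) %% 24
}

# t-based interval from the bootstrap SE: with small panels the percentile
# interval of a non-negative amplitude is too narrow; estimate +/- t * SE
# (df = residual df) restores near-nominal coverage
t_ci <- function(center, boot_vals, df, level = 0.90) {
  s <- stats::sd(boot_vals)
  q <- stats::qt(1 - (1 - level) / 2, df)
  c(center - q * s, center + q * s)
}

#' Two-harmonic cosinor fit of chest surface temperature
#'
#' The minute series is smoothed with a centred 1-h moving average over
#' non-missing minutes, collapsed to an averaged 24-h profile (mean per
#' clock minute across days), and the two-harmonic model (24 h + 12 h
#' components) is fitted by least squares. The acrophase is the clock time
#' at which the full fitted curve attains its maximum (1-min grid);
#' 90% CIs come from a residual bootstrap on the profile.
#'
#' @param temp a `temperature_series` (after ingest masking).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return A `cosinor_fit`: `mesor`, `coef` (M, a1, b1, a2, b2),
#'   `amplitude` (per harmonic), `acrophase`, `ci90_*`, `residual_sd`,
#'   `n_obs`.
#' @export
fit_temperature_cosinor <- function(temp, n_boot = 500L, seed = 1L) {
  v <- temp$values
  ok <- !temp$missing & !is.na(v)
  if (sum(ok) < 72 * 60) stop("need at least 72 h of non-missing data")
  n <- length(v)
  # centred 1-h moving average over present minutes (cumsum trick)
  vv <- ifelse(ok, v, 0)
  cs <- cumsum(vv); cn <- cumsum(as.numeric(ok))
  lo <- pmax(seq_len(n) - 30, 1); hi <- pmin(seq_len(n) + 30, n)
  wsum <- cs[hi] - c(0, cs)[lo]
  wn <- cn[hi] - c(0, cn)[lo]
  sm <- ifelse(wn > 0, wsum / wn, NA_real_)
  sm[!ok] <- NA_real_
  # partial windows at the series boundaries are not centred averages
  sm[c(seq_len(min(30, n)), seq.int(max(1, n - 29), n))] <- NA_real_
  # averaged 24-h profile per clock minute
  minute_of_day <- as.integer(round(clock_hours(series_times(temp)) * 60)) %% 1440
  prof <- tapply(sm, factor(minute_of_day, levels = 0:1439),
                 function(x) mean(x, na.rm = TRUE))
  prof <- as.numeric(prof)
  present <- !is.na(prof) & !is.nan(prof)
  if (mean(present) < 0.5)
    stop("fewer than 50% of clock minutes represented in the daily profile")
  t_h <- (0:1439)[present] / 60
  y <- prof[present]
  fit <- fit_cosinor_core(t_h, y, two_harmonic = TRUE)
  res <- y - fit$fitted
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- fit$fitted + sample(res, length(res), replace = TRUE)
      f <- fit_cosinor_core(t_h, yb, TRUE)
      c(f$mesor, f$amplitude[1], f$acrophase)
    }, numeric(3))
  })
  structure(list(
    model = "two-harmonic", coef = fit$coef, mesor = fit$mesor,
    amplitude = fit$amplitude, acrophase = fit$acrophase,
    ci90_mesor = t_ci(fit$mesor, boots[1, ], length(y) - 5),
    ci90_amplitude = t_ci(fit$amplitude[1], boots[2, ], length(y) - 5),
    ci90_acrophase = wrap_ci(boots[3, ], fit$acrophase, 0.05),
    residual_sd = stats::sd(res), n_obs = length(y)),
    class = "cosinor_fit")
}

#' Single-harmonic 24-h cosinor fit of salivary cortisol
#'
#' Fitted by least squares on the raw sample times (no binning). Panels
#' with fewer than 9 samples over the 2 collection days are rejected as
#' inadequate. Rhythm significance is the zero-amplitude F-test; 90% CIs
#' come from a case bootstrap over samples.
#'
#' @param panel a cortisol [saliva_panel()].
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return A `cosinor_fit` with additionally `f_statistic`, `p_value`,
#'   `significant`.
#' @export
fit_cortisol_cosinor <- function(panel, n_boot = 500L, seed = 1L) {
  stopifnot(inherits(panel, "saliva_panel"))
  if (panel$analyte != "cortisol") stop("panel is not cortisol")
  n <- length(panel$conc)
  if (n < 9) stop("inadequate panel: fewer than 9 samples")
  t_h <- as.numeric(difftime(panel$times, panel$times[1], units = "hours")) +
    clock_hours(panel$times[1])
  y <- panel$conc
  fit <- fit_cosinor_core(t_h, y, two_harmonic = FALSE)
  rss1 <- sum((y - fit$fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  pval <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(t_h[i] %% 24)) < 3) return(c(NA, NA, NA))
      f <- fit_cosinor_core(t_h[i], y[i], FALSE)
      c(f$mesor, f$amplitude[1], f$acrophase)
    }, numeric(3))
  })
  boots <- boots[, stats::complete.cases(t(boots)), drop = FALSE]
  structure(list(
    model = "24h", coef = fit$coef, mesor = fit$mesor,
    amplitude = fit$amplitude, acrophase = fit$acrophase,
    ci90_mesor = t_ci(fit$mesor, boots[1, ], n - 3),
    ci90_amplitude = t_ci(fit$amplitude[1], boots[2, ], n - 3),
    ci90_acrophase = wrap_ci(boots[3, ], fit$acrophase, 0.05),
    residual_sd = sqrt(rss1 / (n - 3)), n_obs = n,
    f_statistic = fstat, p_value = pval, significant = pval < 0.05),
    class = "cosinor_fit")
}

# is a clock hour inside the closed wrap-around night span 22:01-07:00?
in_night_span <- function(h, span = c(22 + 1 / 60, 7)) {
  h >= span[1] | h <= span[2]
}

#' Classify the temperature rhythm
#'
#' `arrhythmic` when the spectral rhythm is not significant; `physiologic`
#' when significant with a dominant period within 24 +/- 2 h and an
#' acrophase inside the closed nocturnal span 22:01-07:00; `abnormal`
#' otherwise (rhythmic but displaced).
#'
#' @param rhythm a [dominant_rhythm()] estimate for the temperature series.
#' @param fit the temperature [fit_temperature_cosinor()] (its acrophase —
#'   the fitted-curve maximum — is the phase used).
#' @return list with `label`, `dominant_period`, `acrophase`.
#' @export
classify_temperature_rhythm <- function(rhythm, fit) {
  label <- if (!rhythm$significant) "arrhythmic"
  else if (abs(rhythm$dominant_period - 24) <= 2 &&
           in_night_span(fit$acrophase)) "physiologic"
  else "abnormal"
  list(label = label, dominant_period = rhythm$dominant_period,
       acrophase = fit$acrophase)
}
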