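# Dim light melatonin onset: baseline thresholds (individual mean + 2 SD
# of 3 consecutive pre-rise samples, or a group-pooled fallback), dim-light
# validity of each sample, and the interpolated threshold-crossing time.

#' Dim-light validity of saliva samples
#'
#' A sample is valid when the mean wrist light over the 30 min before
#' collection is below `lux_cutoff` and no single minute exceeds
#' `spike_mult` times the cutoff. Samples whose prior window is not
#' covered by the light series are flagged indeterminate (`NA`).
#'
#' @param light a `light_series`.
#' @param sample_times `POSIXct` collection times.
#' @param lux_cutoff dim-light cutoff in lux.
#' @param spike_mult single-minute spike multiplier.
#' @return logical vector (TRUE/FALSE/NA per sample).
#' @export
check_dim_light <- function(light, sample_times, lux_cutoff = 50,
                            spike_mult = 4) {
  times <- series_times(light)
  vapply(sample_times, function(ts) {
    sel <- times > ts - 30 * 60 & times <= ts
    v <- light$values[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA)
    mean(v) < lux_cutoff && max(v) <= spike_mult * lux_cutoff
  }, logical(1))
}

#' Baseline threshold arithmetic
#'
#' Mean plus twice the sample SD (n-1 denominator) of a set of baseline
#' melatonin values.
#'
#' @param values baseline concentrations.
#' @return threshold in the same units.
#' @export
baseline_threshold <- function(values) {
  mean(values) + 2 * stats::sd(values)
}

# index at which the first sustained rise starts: two successive
# increases totaling more than `rise_frac` of `ref_mean`
rise_start <- function(conc, ref_mean, rise_frac) {
  n <- length(conc)
  for (k in seq_len(max(n - 2, 0))) {
    if (conc[k + 1] > conc[k] && conc[k + 2] > conc[k + 1] &&
        (conc[k + 2] - conc[k]) > rise_frac * ref_mean)
      return(k)
  }
  NA_integer_
}

#' Individual melatonin baseline threshold
#'
#' Finds the earliest run of 3 consecutive samples that (i) ends at or
#' before the start of the first sustained rise (two successive increases
#' totaling more than `rise_frac` of the run mean) and (ii) has
#' coefficient of variation below `cv_max`; the threshold is the run mean
#' plus twice the run sample SD. A run preceded by a sample far below its
#' own level is rejected as a post-rise plateau (a rise completed between
#' the first samples leaves no detectable pair of increases).
#'
#' @param panel a melatonin [saliva_panel()].
#' @param rise_frac sustained-rise fraction of the run mean.
#' @param cv_max maximum baseline coefficient of variation.
#' @return list with `threshold` (`NA` when no qualifying run exists,
#'   triggering the pooled fallback), `baseline_samples`, `run_start`.
#' @export
individual_threshold <- function(panel, rise_frac = 0.25, cv_max = 0.33) {
  stopifnot(inherits(panel, "saliva_panel"))
  if (panel$analyte != "melatonin") stop("panel is not melatonin")
  conc <- panel$conc
  n <- length(conc)
  if (n < 3)
    return(list(threshold = NA_real_, baseline_samples = NULL,
                run_start = NA_integer_))
  for (i in seq_len(n - 2)) {
    run <- conc[i:(i + 2)]
    m <- mean(run)
    if (m <= 0) next
    if (stats::sd(run) / m >= cv_max) next
    # an earlier sample far below the run level means the run sits on a
    # post-rise plateau, not a pre-rise baseline
    if (i > 1 && any(conc[seq_len(i - 1)] < m * (1 - rise_frac))) next
    k <- rise_start(conc, m, rise_frac)
    if (!is.na(k) && k < i + 2) next   # run not fully before the rise
    return(list(threshold = baseline_threshold(run),
                baseline_samples = run, run_start = i))
  }
  list(threshold = NA_real_, baseline_samples = NULL,
       run_start = NA_integer_)
}

#' Group-pooled melatonin baseline threshold
#'
#' Pools the qualifying individual baseline values across the subjects of
#' one group and returns the pooled mean plus twice the pooled sample SD.
#' Distinct thresholds are intended per group (patients vs controls).
#'
#' @param panels list of melatonin panels from one group.
#' @param rise_frac,cv_max forwarded to [individual_threshold()].
#' @return list with `threshold`, `n_contributors`, `values` (pooled
#'   baseline values).
#' @export
pooled_threshold <- function(panels, rise_frac = 0.25, cv_max = 0.33) {
  base <- lapply(panels, function(p)
    individual_threshold(p, rise_frac, cv_max)$baseline_samples)
  base <- base[!vapply(base, is.null, logical(1))]
  if (length(base) < 2)
    stop("need at least 2 subjects with an individual baseline")
  values <- unlist(base)
  list(threshold = baseline_threshold(values),
       n_contributors = length(base), values = values)
}

#' Compute the dim light melatonin onset
#'
#' DLMO is the first time the concentration crosses from at or below the
#' threshold to above it and stays above for all subsequent samples; the
#' crossing time is linearly interpolated between the flanking samples.
#'
#' @param panel a melatonin [saliva_panel()].
#' @param threshold threshold concentration (> 0).
#' @param validity optional per-sample dim-light flags from
#'   [check_dim_light()].
#' @param baseline_source `"individual"` or `"pooled"`.
#' @return A `dlmo_result`: `threshold`, `dlmo_time` (`POSIXct` or `NA`),
#'   `dlmo_clock_h`, `determined`, `baseline_source`, `dim_light_valid`,
#'   `flags` (character vector).
#' @export
compute_dlmo <- function(panel, threshold, validity = NULL,
                         baseline_source = "individual") {
  stopifnot(threshold > 0)
  conc <- panel$conc
  n <- length(conc)
  if (n < 2) stop("need at least 2 samples")
  flags <- character(0)
  if (conc[1] > threshold) {
    return(structure(list(threshold = threshold, dlmo_time = NA,
                          dlmo_clock_h = NA_real_, determined = FALSE,
                          baseline_source = baseline_source,
                          dim_light_valid = validity,
                          flags = "onset_precedes_window"),
                     class = "dlmo_result"))
  }
  cross <- NA_integer_
  for (k in seq_len(n - 1)) {
    if (conc[k] <= threshold && conc[k + 1] > threshold &&
        all(conc[(k + 1):n] > threshold)) { cross <- k; break }
  }
  if (is.na(cross)) {
    return(structure(list(threshold = threshold, dlmo_time = NA,
                          dlmo_clock_h = NA_real_, determined = FALSE,
                          baseline_source = baseline_source,
                          dim_light_valid = validity,
                          flags = "never_exceeds_threshold"),
                     class = "dlmo_result"))
  }
  t1 <- panel$times[cross]; t2 <- panel$times[cross + 1]
  frac <- (threshold - conc[cross]) / (conc[cross + 1] - conc[cross])
  dlmo_time <- t1 + frac * as.numeric(difftime(t2, t1, units = "secs"))
  if (!is.null(validity)) {
    vv <- validity[c(cross, cross + 1)]
    if (any(!vv, na.rm = TRUE))
      flags <- c(flags, "crossing_flanked_by_bright_light")
  }
  structure(list(threshold = threshold, dlmo_time = dlmo_time,
                 dlmo_clock_h = clock_hours(dlmo_time), determined = TRUE,
                 baseline_source = baseline_source,
                 dim_light_valid = validity, flags = flags),
            class = "dlmo_result")
}
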