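#' Minute-resolution sensor series
#'
#' Light-weight containers for the minute-indexed signals the pipeline
#' consumes: chest activity counts (acc/min), chest surface temperature
#' (degrees C) and wrist light exposure (lux). A series stores its start
#' time, a fixed step, the values and a logical missing mask; values at
#' masked positions are `NA`.
#'
#' @param start `POSIXct` timestamp of the first sample.
#' @param values numeric vector of samples.
#' @param missing logical mask, same length as `values`; defaults to
#'   `is.na(values)`.
#' @param step sampling step in seconds (default 60).
#' @param kind one of `"activity"`, `"temperature"`, `"light"`.
#' @return An object of class `c("<kind>_series", "minute_series")`.
#' @export
minute_series <- function(start, values, missing = is.na(values),
                          step = 60, kind = "activity") {
  kind <- match.arg(kind, c("activity", "temperature", "light"))
  stopifnot(inherits(start, "POSIXct"), length(values) == length(missing))
  values <- as.numeric(values)
  missing <- as.logical(missing) | is.na(values)
  values[missing] <- NA_real_
  ok <- values[!missing]
  if (kind %in% c("activity", "light") && any(ok < 0))
    stop(kind, " values must be non-negative")
  structure(
    list(kind = kind, start = start, step = as.numeric(step),
         values = values, missing = missing),
    class = c(paste0(kind, "_series"), "minute_series"))
}

#' @rdname minute_series
#' @export
activity_series <- function(start, values, missing = is.na(values), step = 60)
  minute_series(start, values, missing, step, kind = "activity")

#' @rdname minute_series
#' @export
temperature_series <- function(start, values, missing = is.na(values), step = 60)
  minute_series(start, values, missing, step, kind = "temperature")

#' @rdname minute_series
#' @export
light_series <- function(start, values, missing = is.na(values), step = 60)
  minute_series(start, values, missing, step, kind = "light")

#' @export
length.minute_series <- function(x) length(x$values)

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<%s series: %d x %gs from %s, %.1f%% missing>\n",
              x$kind, length(x$values), x$step,
              format(x$start, "%Y-%m-%d %H:%M"),
              100 * mean(x$missing)))
  invisible(x)
}

#' Sample timestamps of a series
#' @param x a `minute_series` or binned series.
#' @return `POSIXct` vector, one timestamp per sample (bin start times for
#'   binned series).
#' @export
series_times <- function(x) x$start + (seq_along(x$values) - 1) * x$step

#' Clock time in hours
#' @param t `POSIXct` vector.
#' @return numeric hours since local midnight, in `[0, 24)`.
#' @export
clock_hours <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  (lt$hour + lt$min / 60 + lt$sec / 3600) %% 24
}

#' Noon-to-noon study-day index
#'
#' All per-day quantities use a noon-to-noon day axis so that a nocturnal
#' rest episode is never split across two days. Day 1 spans from the first
#' noon at or before the reference time to the following noon.
#'
#' @param t `POSIXct` vector to index.
#' @param origin `POSIXct` reference (typically the series start).
#' @return integer study-day numbers (1-based).
#' @export
study_day <- function(t, origin) {
  noon0 <- as.POSIXct(trunc(as.POSIXlt(origin, tz = "UTC"), "days"),
                      tz = "UTC") + 12 * 3600
  if (noon0 > origin) noon0 <- noon0 - 86400
  1L + as.integer(floor(as.numeric(difftime(t, noon0, units = "hours")) / 24))
}

#' Salivary hormone sample panel
#'
#' @param analyte `"cortisol"` (nmol/L) or `"melatonin"` (pg/mL).
#' @param times `POSIXct` collection timestamps, strictly increasing.
#' @param conc non-negative finite concentrations.
#' @return A `saliva_panel` object.
#' @export
saliva_panel <- function(analyte, times, conc) {
  analyte <- match.arg(analyte, c("cortisol", "melatonin"))
  stopifnot(inherits(times, "POSIXct"), length(times) == length(conc))
  if (is.unsorted(times, strictly = TRUE))
    stop("saliva sample timestamps must be strictly increasing")
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  structure(list(analyte = analyte, times = times, conc = conc,
                 units = if (analyte == "cortisol") "nmol/L" else "pg/mL"),
            class = "saliva_panel")
}

#' @export
print.saliva_panel <- function(x, ...) {
  cat(sprintf("<%s panel: %d samples, %s>\n", x$analyte, length(x$conc),
              x$units))
  invisible(x)
}

#' Daily lifestyle diary
#'
#' One row per study day with self-reported retiring and rising clock
#' times, exercise spans and meal times. Retiring must precede rising on
#' the noon-to-noon day axis.
#'
#' @param day integer study-day numbers.
#' @param retiring,rising clock hours in `[0, 24)`.
#' @param exercise list (one element per day) of two-column matrices of
#'   clock-hour spans, or `NULL` entries.
#' @param meals list of numeric clock-hour vectors, or `NULL` entries.
#' @return A `diary_log` data frame.
#' @export
diary_log <- function(day, retiring, rising, exercise = NULL, meals = NULL) {
  n <- length(day)
  stopifnot(length(retiring) == n, length(rising) == n)
  if (is.null(exercise)) exercise <- rep(list(NULL), n)
  if (is.null(meals)) meals <- rep(list(NULL), n)
  # on the noon-to-noon axis retiring (evening) precedes rising (morning)
  ret_ax <- ifelse(retiring >= 12, retiring - 12, retiring + 12)
  ris_ax <- ifelse(rising >= 12, rising - 12, rising + 12)
  if (any(ret_ax >= ris_ax))
    stop("retiring must precede rising on the noon-to-noon day axis")
  out <- data.frame(day = as.integer(day), retiring = retiring,
                    rising = rising)
  out$exercise <- exercise
  out$meals <- meals
  class(out) <- c("diary_log", "data.frame")
  out
}

#' In-bed spans from a diary
#'
#' Converts per-day retiring/rising clock times into absolute in-bed
#' intervals on the recording timeline.
#'
#' @param diary a [diary_log()].
#' @param origin `POSIXct` recording start (defines study day 1).
#' @param provenance `"diary"` or `"hmm"`.
#' @return A `bed_spans` data frame with columns `day`, `bed_start`,
#'   `bed_end` (`POSIXct`) and attribute `provenance`.
#' @export
bed_spans <- function(diary, origin, provenance = "diary") {
  noon0 <- as.POSIXct(trunc(as.POSIXlt(origin, tz = "UTC"), "days"),
                      tz = "UTC") + 12 * 3600
  if (noon0 > origin) noon0 <- noon0 - 86400
  day_start <- noon0 + (diary$day - 1) * 86400
  ret_ax <- ifelse(diary$retiring >= 12, diary$retiring - 12,
                   diary$retiring + 12)
  ris_ax <- ifelse(diary$rising >= 12, diary$rising - 12, diary$rising + 12)
  if (any(ris_ax - ret_ax > 18)) stop("in-bed interval exceeds 18 h")
  out <- data.frame(day = diary$day,
                    bed_start = day_start + ret_ax * 3600,
                    bed_end = day_start + ris_ax * 3600)
  if (any(utils::head(out$bed_end, -1) > utils::tail(out$bed_start, -1)))
    stop("in-bed intervals overlap")
  attr(out, "provenance") <- provenance
  class(out) <- c("bed_spans", "data.frame")
  out
}

#' Circular mean of clock hours
#' @param h clock hours in `[0, 24)`.
#' @param w optional non-negative weights.
#' @return circular mean in `[0, 24)`, or `NA` if undefined.
#' @export
circular_mean_hours <- function(h, w = NULL) {
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(h))
  a <- h / 24 * 2 * pi
  m <- atan2(sum(w * sin(a)), sum(w * cos(a)))
  (m / (2 * pi) * 24) %% 24
}
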