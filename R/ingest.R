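# Ingest: file reading, off-body span detection, aggregation and
# interpolation. All sensor files are `timestamp,value` CSVs with ISO-8601
# timestamps on a fixed 1-min grid; gaps become missing-masked entries.

parse_iso <- function(x) {
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  bad <- is.na(t)
  if (any(bad))
    t[bad] <- as.POSIXct(x[bad], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(t)) stop("unparseable timestamp at row ", which(is.na(t))[1])
  t
}

#' Read a minute-resolution sensor CSV
#'
#' Expects a `timestamp,value` header. Gaps in the minute grid become
#' missing-masked entries; duplicate or non-monotone timestamps are
#' rejected with the first offending row named.
#'
#' @param path CSV file path.
#' @param kind `"activity"`, `"temperature"` or `"light"`.
#' @return A [minute_series()] of the requested kind.
#' @export
read_series <- function(path, kind = c("activity", "temperature", "light")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "value") %in% names(df)))
    stop("expected header 'timestamp,value' in ", path)
  t <- parse_iso(df$timestamp)
  d <- diff(as.numeric(t))
  if (any(d == 0)) stop("duplicate timestamp at row ", which(d == 0)[1] + 1)
  if (any(d < 0)) stop("non-monotone timestamp at row ", which(d < 0)[1] + 1)
  start <- t[1]
  idx <- as.integer(round(as.numeric(difftime(t, start, units = "secs")) / 60))
  if (any(diff(idx) == 0)) stop("timestamps off the 1-min grid in ", path)
  n <- idx[length(idx)] + 1L
  values <- rep(NA_real_, n)
  values[idx + 1L] <- as.numeric(df$value)
  minute_series(start, values, kind = kind)
}

#' Detect off-body spans from temperature decay
#'
#' Minutes where temperature sits within `delta_c` of room temperature for
#' at least `plateau_min` consecutive minutes are flagged as off-body
#' (sensor removed, e.g. for a shower), together with the preceding
#' monotone decay limb. The flag is applied to both the temperature and
#' activity masks.
#'
#' @param temp a `temperature_series`.
#' @param activity an `activity_series` on the same grid.
#' @param room_temp_c assumed ambient temperature.
#' @param delta_c tolerance defining "near room temperature".
#' @param plateau_min minimum plateau length in minutes.
#' @param monotone_min maximum backward extension over the decay limb.
#' @return list with `mask` (combined logical), and masked copies
#'   `temperature` and `activity`.
#' @export
detect_missing_spans <- function(temp, activity, room_temp_c = 21,
                                 delta_c = 2, plateau_min = 10,
                                 monotone_min = 5) {
  stopifnot(length(temp) == length(activity))
  v <- temp$values
  if (all(is.na(v)) && all(is.na(activity$values)))
    stop("no analyzable data")
  near <- !is.na(v) & v <= room_temp_c + delta_c
  flag <- rep(FALSE, length(v))
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < plateau_min) next
    s <- starts[i]; e <- ends[i]
    flag[s:e] <- TRUE
    # extend backwards over the strictly decreasing decay limb
    k <- s - 1L; steps <- 0L
    while (k >= 1L && steps < monotone_min && !is.na(v[k]) &&
           !is.na(v[k + 1L]) && v[k] > v[k + 1L]) {
      flag[k] <- TRUE
      k <- k - 1L; steps <- steps + 1L
    }
  }
  mask <- flag | temp$missing | activity$missing
  tv <- temp$values; tv[mask] <- NA_real_
  av <- activity$values; av[mask] <- NA_real_
  list(mask = mask,
       temperature = temperature_series(temp$start, tv, mask),
       activity = activity_series(activity$start, av, mask))
}

#' Aggregate a minute series into fixed bins
#'
#' Bins with more than `max_missing_frac` missing minutes are missing;
#' otherwise the statistic is taken over the present minutes (mean
#' preserves acc/min units).
#'
#' @param series a [minute_series()].
#' @param bin_min bin width in minutes; must divide 24 h.
#' @param stat `"mean"` or `"sum"`.
#' @param max_missing_frac completeness rule per bin.
#' @return A `binned_series` list (`kind`, `start`, `step` seconds,
#'   `values`, `missing`).
#' @export
aggregate_series <- function(series, bin_min, stat = c("mean", "sum"),
                             max_missing_frac = 0.5) {
  stat <- match.arg(stat)
  step_min <- series$step / 60
  if (bin_min < step_min) stop("bin is finer than the series step")
  if (1440 %% bin_min != 0) stop("bin must divide evenly into 24 h")
  per <- as.integer(bin_min / step_min)
  n_bin <- floor(length(series$values) / per)
  idx <- rep(seq_len(n_bin), each = per)
  v <- series$values[seq_len(n_bin * per)]
  miss <- series$missing[seq_len(n_bin * per)]
  n_miss <- tapply(miss, idx, sum)
  f <- if (stat == "mean") function(x) mean(x, na.rm = TRUE)
       else function(x) sum(x, na.rm = TRUE)
  vals <- as.numeric(tapply(v, idx, f))
  bad <- as.numeric(n_miss) / per > max_missing_frac
  vals[bad] <- NA_real_
  structure(list(kind = series$kind, start = series$start,
                 step = bin_min * 60, values = vals, missing = bad),
            class = "binned_series")
}

#' Linearly interpolate missing bins
#'
#' Interior gaps are filled by linear interpolation; leading/trailing gaps
#' by nearest-value extension. The fraction interpolated is attached as an
#' attribute and a warning is raised when it exceeds `warn_frac`.
#'
#' @param binned a `binned_series`.
#' @param warn_frac threshold for the missingness warning.
#' @return The completed series with attribute `fraction_interpolated`.
#' @export
interpolate_missing <- function(binned, warn_frac = 0.3) {
  v <- binned$values
  miss <- is.na(v) | binned$missing
  frac <- mean(miss)
  if (all(miss)) stop("no analyzable data")
  if (any(miss)) {
    x <- seq_along(v)
    v <- stats::approx(x[!miss], v[!miss], xout = x, rule = 2)$y
  }
  if (frac > warn_frac)
    warning(sprintf("%.0f%% of bins were interpolated", 100 * frac))
  out <- binned
  out$values <- v
  out$missing <- rep(FALSE, length(v))
  attr(out, "fraction_interpolated") <- frac
  out
}

# ---- subject directory I/O ----

fmt_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write a synthetic record as a subject directory
#'
#' Emits the same CSV dialects [read_subject_dir()] consumes: one
#' `timestamp,value` file per sensor, a diary CSV
#' (`date,retiring,rising,exercise_spans,meals` with `;`-separated spans)
#' and a pooled saliva CSV (`timestamp,analyte,concentration`).
#'
#' @param record a `synthetic_record`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_dir <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sig in c("activity", "temperature", "light")) {
    s <- record[[sig]]
    keep <- !s$missing
    utils::write.csv(
      data.frame(timestamp = fmt_iso(series_times(s)[keep]),
                 value = s$values[keep]),
      file.path(dir, paste0(sig, ".csv")), row.names = FALSE)
  }
  d <- record$diary
  span_str <- vapply(d$exercise, function(m) {
    if (is.null(m)) "" else paste(sprintf("%.2f-%.2f", m[, 1], m[, 2]),
                                  collapse = ";")
  }, character(1))
  meal_str <- vapply(d$meals, function(m) {
    if (is.null(m)) "" else paste(sprintf("%.2f", m), collapse = ";")
  }, character(1))
  day0 <- as.Date(record$activity$start)
  utils::write.csv(
    data.frame(date = day0 + d$day - 1, retiring = round(d$retiring, 3),
               rising = round(d$rising, 3), exercise_spans = span_str,
               meals = meal_str),
    file.path(dir, "diary.csv"), row.names = FALSE)
  sal <- rbind(
    data.frame(timestamp = fmt_iso(record$cortisol$times),
               analyte = "cortisol", concentration = record$cortisol$conc),
    data.frame(timestamp = fmt_iso(record$melatonin$times),
               analyte = "melatonin", concentration = record$melatonin$conc))
  utils::write.csv(sal, file.path(dir, "saliva.csv"), row.names = FALSE)
  utils::write.csv(record$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a subject directory
#'
#' @param dir directory written by [write_subject_dir()] (or following the
#'   same contract). Missing saliva/diary files yield `NULL` entries.
#' @return list with `activity`, `temperature`, `light`, `diary`,
#'   `cortisol`, `melatonin`, `covariates` (entries `NULL` when absent).
#' @export
read_subject_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(activity = NULL, temperature = NULL, light = NULL,
              diary = NULL, cortisol = NULL, melatonin = NULL,
              covariates = NULL)
  for (sig in c("activity", "temperature", "light"))
    if (file.exists(p(paste0(sig, ".csv"))))
      out[[sig]] <- read_series(p(paste0(sig, ".csv")), sig)
  if (file.exists(p("diary.csv"))) {
    d <- utils::read.csv(p("diary.csv"), stringsAsFactors = FALSE)
    parse_spans <- function(s) {
      if (is.na(s) || s == "") return(NULL)
      parts <- strsplit(strsplit(s, ";")[[1]], "-")
      matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
    }
    parse_meals <- function(s) {
      if (is.na(s) || s == "") return(NULL)
      as.numeric(strsplit(s, ";")[[1]])
    }
    out$diary <- diary_log(seq_len(nrow(d)), d$retiring, d$rising,
                           lapply(d$exercise_spans, parse_spans),
                           lapply(d$meals, parse_meals))
  }
  if (file.exists(p("saliva.csv"))) {
    s <- utils::read.csv(p("saliva.csv"), stringsAsFactors = FALSE)
    for (an in c("cortisol", "melatonin")) {
      sub <- s[s$analyte == an, ]
      if (nrow(sub))
        out[[an]] <- saliva_panel(an, parse_iso(sub$timestamp),
                                  sub$concentration)
    }
  }
  if (file.exists(p("covariates.csv")))
    out$covariates <- utils::read.csv(p("covariates.csv"),
                                      stringsAsFactors = FALSE)
  out
}
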