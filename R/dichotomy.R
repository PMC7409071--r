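# Dichotomy index I<O: percentage of in-bed activity counts per minute
# strictly below the median out-of-bed activity count, and the 97.5%
# low/high classification on the first 72 h.

#' Compute the dichotomy index I<O
#'
#' Over the given window, the out-of-bed pool is every non-missing minute
#' outside the in-bed spans; its median is the single reference value.
#' `io_percent` is 100 x the fraction of non-missing in-bed minutes whose
#' count is strictly below that median (ties count as not below).
#'
#' @param activity an `activity_series`.
#' @param beds a [bed_spans()] data frame.
#' @param window `POSIXct` length-2 `(start, end)`; default spans the
#'   whole series.
#' @return An `io_result` list: `io_percent`, `window`, `n_in_minutes`,
#'   `n_out_minutes`, `out_median`, `category` (set only for windows of
#'   72 h or more, against the 97.5% threshold), `degenerate_out_median`
#'   flag.
#' @export
compute_io <- function(activity, beds, window = NULL) {
  times <- series_times(activity)
  if (is.null(window))
    window <- c(times[1], times[length(times)] + activity$step)
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stop("window contains no data")
  in_bed <- in_bed_flag(times, beds) & sel
  out_bed <- !in_bed_flag(times, beds) & sel
  ok <- !activity$missing
  complete_interval <- any(beds$bed_start >= window[1] &
                             beds$bed_end <= window[2])
  if (!any(in_bed)) stop("no rest interval inside window")
  if (!complete_interval)
    stop("no complete in-bed interval inside window")
  n_out <- sum(out_bed & ok)
  if (n_out == 0) stop("all out-of-bed minutes missing")
  if (n_out < 4 * 60)
    stop("fewer than 4 h of usable out-of-bed minutes in window")
  out_median <- stats::median(activity$values[out_bed & ok])
  in_counts <- activity$values[in_bed & ok]
  degenerate <- out_median == 0
  io <- if (degenerate) 0 else 100 * mean(in_counts < out_median)
  hours <- as.numeric(difftime(window[2], window[1], units = "hours"))
  structure(list(io_percent = io, window = window,
                 n_in_minutes = length(in_counts), n_out_minutes = n_out,
                 out_median = out_median,
                 category = if (hours >= 72) classify_io(io) else NA_character_,
                 degenerate_out_median = degenerate),
            class = "io_result")
}

#' Classify a 72-h dichotomy index
#'
#' Values at or below 97.5% are `"low"` (disrupted rest-activity rhythm),
#' values strictly above are `"high"`.
#'
#' @param io_72h I<O percentage in `[0, 100]`.
#' @param threshold classification threshold (default 97.5).
#' @return `"low"` or `"high"`.
#' @export
classify_io <- function(io_72h, threshold = 97.5) {
  if (is.na(io_72h) || io_72h < 0 || io_72h > 100)
    stop("io_72h must lie in [0, 100]")
  if (io_72h <= threshold) "low" else "high"
}
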