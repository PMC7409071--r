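#' Analysis configuration
#'
#' Single place for every tunable threshold, tolerance, resample count and
#' seed used by the pipeline. Defaults reproduce the standard analysis;
#' override entries via `...` (nested lists are merged shallowly).
#'
#' @param ... named overrides, e.g. `spectral = list(n_resample = 100)`.
#' @return A nested list of class `circarest_config`.
#' @examples
#' cfg <- circarest_config(dlmo = list(lux_cutoff = 30))
#' cfg$dlmo$lux_cutoff
#' @export
circarest_config <- function(...) {
  cfg <- list(
    seed = 1L,
    ingest = list(
      room_temp_c = 21,       # assumed indoor ambient temperature
      off_body_delta_c = 2,   # "near room temperature" tolerance
      plateau_min = 10,       # minimum off-body plateau length (min)
      monotone_min = 5,       # backward scan window for the decay limb
      temp_band = c(15, 42),  # plausibility band for on-body skin temp
      bin_missing_frac = 0.5, # bins with more missing than this are missing
      interp_warn_frac = 0.3  # warn when more than this was interpolated
    ),
    io = list(threshold = 97.5, min_out_hours = 4),
    hmm = list(
      n_states = 3L, bin_min = 5, max_iter = 500L, tol = 1e-6,
      n_restarts = 5L, degenerate_frac = 0.01,
      night_span = c(22 + 1 / 60, 7)   # 22:01-07:00 nocturnal window
    ),
    spectral = list(
      period_grid = seq(6, 30, by = 0.1), n_resample = 500L,
      n_scramble = 200L, ci_level = 0.90
    ),
    cosinor = list(n_boot = 500L, min_hours = 72,
                   min_profile_frac = 0.5),
    dlmo = list(
      lux_cutoff = 50, lux_spike_mult = 4, rise_frac = 0.25,
      baseline_cv_max = 0.33
    ),
    determinants = list(max_predictors = 4L,
                        fisher_convention = "minlike")
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "circarest_config")
}
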