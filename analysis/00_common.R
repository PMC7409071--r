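# Shared settings for the analysis scripts: the cohort composition
# mirrors the study population (25 gastrointestinal cancer patients of
# whom 13 carry the disrupted phenotype, 33 age/sex-stratified controls
# of whom 4 are disrupted), recorded for 7 days with about one off-body
# (shower) span per day.

library(circarest)

COHORT_SEED <- 20200106L
COHORT_SPEC <- list(patients = c(disrupted = 13, robust = 12),
                    controls = c(disrupted = 4, robust = 29))

# resampling sizes for the cohort sweep: enough for stable flags and
# intervals at interactive runtimes (the package defaults are higher)
ANALYSIS_CONFIG <- circarest_config(
  seed = COHORT_SEED,
  spectral = list(n_resample = 200L, n_scramble = 200L),
  cosinor = list(n_boot = 200L))

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}

make_cohort <- function() {
  generate_cohort(COHORT_SPEC, seed = COHORT_SEED, days = 7,
                  missing_events_per_day = 1)
}
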