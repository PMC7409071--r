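#!/usr/bin/env Rscript
# Rest-activity circadian quantification: the dichotomy index over the
# first 72 h and the full week, the 97.5% low/high classification, the
# 3-state HMM quantifiers (P1-1, RI, center-of-rest, state mid-levels,
# sleep-duration variability) and r24.

source("analysis/00_common.R")

coh <- make_cohort()
rows <- lapply(coh$records, function(r) {
  sp <- detect_missing_spans(r$temperature, r$activity)
  act <- sp$activity
  beds <- bed_spans(r$diary, act$start)
  io72 <- compute_io(act, beds, c(act$start, act$start + 72 * 3600))
  io <- compute_io(act, beds)
  act5 <- aggregate_series(act, 5, "mean")
  m <- fit_hmm(act5, seed = ANALYSIS_CONFIG$seed)
  dec <- decode_states(m, act5)
  d <- derive_metrics(m, dec)
  r24 <- autocorr24(aggregate_series(act, 60, "mean"))$r24
  data.frame(subject_id = r$covariates$subject_id,
             group = r$covariates$group,
             phenotype = r$covariates$phenotype,
             io_72h = io72$io_percent, category = io72$category,
             io_7d = io$io_percent, p11 = d$p11, ri = d$ri,
             r24 = r24, center_of_rest = d$center_of_rest,
             mid_MA = d$mid_MA, mid_HA = d$mid_HA,
             sleep_duration_sd = d$sleep_duration_sd)
})
tab <- do.call(rbind, rows)
write.csv(tab, results_path("02_rest_activity.csv"), row.names = FALSE)

counts <- table(tab$group, tab$category)
print(counts)
ft <- fisher_exact_2x2(counts[, c("low", "high")])
cat(sprintf("low-I<O prevalence, patients vs controls: Fisher p = %.4g\n",
            ft$p))
pat <- tab[tab$group == "patient", ]
for (v in c("io_7d", "p11", "ri", "r24", "mid_HA", "sleep_duration_sd")) {
  gc <- group_compare(pat[[v]][pat$category == "low"],
                      pat[[v]][pat$category == "high"], "welch")
  cat(sprintf("  %-18s low median %8.3f  high median %8.3f  Welch p = %.3g\n",
              v, median(pat[[v]][pat$category == "low"], na.rm = TRUE),
              median(pat[[v]][pat$category == "high"], na.rm = TRUE),
              gc$p))
}
cat("wrote results/02_rest_activity.csv\n")
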