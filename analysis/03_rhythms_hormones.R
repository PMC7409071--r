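#!/usr/bin/env Rscript
# Rhythm estimation beyond rest-activity: spectral dominant period /
# amplitude / acrophase for activity and chest temperature, the
# two-harmonic temperature cosinor with the physiologic / abnormal /
# arrhythmic classification, the 24-h cortisol cosinor, and DLMO with
# individual or group-pooled baseline thresholds.

source("analysis/00_common.R")

coh <- make_cohort()
cfg <- ANALYSIS_CONFIG

groups <- vapply(coh$records, function(r)
  as.character(r$covariates$group), character(1))
pooled <- lapply(split(coh$records, groups), function(rs)
  tryCatch(pooled_threshold(lapply(rs, `[[`, "melatonin"))$threshold,
           error = function(e) NA_real_))
cat(sprintf("pooled melatonin thresholds: patients %.2f pg/mL, controls %.2f pg/mL\n",
            pooled$patient, pooled$control))

rows <- lapply(coh$records, function(r) {
  rep <- run_subject(r, cfg,
                     pooled_melatonin_threshold =
                       pooled[[as.character(r$covariates$group)]])
  rr <- report_row(rep)
  rr$temp_class <- if (!is.null(rep$temp_class)) rep$temp_class$label else NA
  rr$dlmo_source <- if (!is.null(rep$dlmo)) rep$dlmo$baseline_source else NA
  rr
})
tab <- do.call(rbind, rows)
write.csv(tab, results_path("03_rhythms_hormones.csv"), row.names = FALSE)

pat <- tab[tab$group == "patient", ]
cls <- table(pat$category, pat$temp_class)
print(cls)
phys <- cbind(physiologic = tapply(pat$temp_physiologic, pat$category, sum,
                                   na.rm = TRUE),
              other = tapply(1 - pat$temp_physiologic, pat$category, sum,
                             na.rm = TRUE))
if (all(dim(phys) == c(2, 2)) && !anyNA(phys))
  cat(sprintf("physiologic temperature rhythm by category: Fisher p = %.4g\n",
              fisher_exact_2x2(phys)$p))
cat(sprintf("significant cortisol rhythm: %d/%d subjects\n",
            sum(tab$cortisol_significant, na.rm = TRUE),
            sum(!is.na(tab$cortisol_significant))))
cat(sprintf("DLMO determined for %d/%d subjects (median %.2f h patients, %.2f h controls)\n",
            sum(!is.na(tab$dlmo_h)), nrow(tab),
            median(tab$dlmo_h[tab$group == "patient"], na.rm = TRUE),
            median(tab$dlmo_h[tab$group == "control"], na.rm = TRUE)))
cat("wrote results/03_rhythms_hormones.csv\n")
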