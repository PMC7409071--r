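# Per-subject orchestration and cohort-level reporting: ingest ->
# dichotomy -> HMM -> spectral -> cosinor -> DLMO, then group contrasts,
# the RACR correlation matrix and the determinant analysis.

try_stage <- function(expr, warnings, stage) {
  tryCatch(list(value = expr, warnings = warnings),
           error = function(e) {
             list(value = NULL,
                  warnings = c(warnings, paste0(stage, ": ", conditionMessage(e))))
           })
}

#' Run the full analysis for one subject
#'
#' Executes ingest (off-body span removal), the 72-h and full-window
#' dichotomy index, the rest-activity HMM with derived quantifiers,
#' spectral rhythm estimation and r24 for activity and temperature, the
#' temperature and cortisol cosinor fits, the temperature rhythm
#' classification and DLMO. Stages the protocol tolerates missing (e.g.
#' an inadequate cortisol panel) downgrade to warnings; only unusable
#' activity aborts.
#'
#' @param subject a `synthetic_record`, a subject directory path, or a
#'   [read_subject_dir()] list.
#' @param config a [circarest_config()].
#' @param pooled_melatonin_threshold optional group-pooled threshold used
#'   when the individual baseline is unavailable.
#' @return A `subject_report` list; absent stages are `NULL` with an
#'   explanatory entry in `warnings`.
#' @export
run_subject <- function(subject, config = circarest_config(),
                        pooled_melatonin_threshold = NULL) {
  if (is.character(subject)) subject <- read_subject_dir(subject)
  if (is.null(subject$activity)) stop("no activity data: cannot analyze")
  warns <- character(0)
  seed <- config$seed

  # ingest: off-body spans from temperature decay
  activity <- subject$activity
  temperature <- subject$temperature
  if (!is.null(temperature)) {
    ig <- config$ingest
    sp <- detect_missing_spans(temperature, activity,
                               room_temp_c = ig$room_temp_c,
                               delta_c = ig$off_body_delta_c,
                               plateau_min = ig$plateau_min,
                               monotone_min = ig$monotone_min)
    activity <- sp$activity
    temperature <- sp$temperature
  }
  completeness <- 100 * mean(!activity$missing)

  # HMM on 5-min aggregated activity
  act5 <- aggregate_series(activity, config$hmm$bin_min, "mean",
                           config$ingest$bin_missing_frac)
  st <- try_stage({
    model <- fit_hmm(act5, harmonic = FALSE, seed = seed,
                     n_states = config$hmm$n_states,
                     n_restarts = config$hmm$n_restarts,
                     max_iter = config$hmm$max_iter, tol = config$hmm$tol,
                     degenerate_frac = config$hmm$degenerate_frac)
    dec <- decode_states(model, act5)
    list(model = model, decoding = dec,
         derived = derive_metrics(model, dec))
  }, warns, "hmm")
  warns <- st$warnings
  hmm <- st$value

  # bed spans: diary first, HMM sleep windows as fallback
  beds <- NULL
  if (!is.null(subject$diary)) {
    beds <- bed_spans(subject$diary, activity$start, "diary")
  } else if (!is.null(hmm) && nrow(hmm$derived$sleep_windows)) {
    w <- hmm$derived$sleep_windows
    beds <- data.frame(day = w$day, bed_start = w$onset, bed_end = w$wake)
    attr(beds, "provenance") <- "hmm"
    warns <- c(warns, "beds: diary absent, HMM rest windows used")
  }

  io_72h <- io_full <- NULL
  if (!is.null(beds)) {
    end72 <- activity$start + 72 * 3600
    st <- try_stage(compute_io(activity, beds,
                               c(activity$start, end72)), warns, "io72")
    warns <- st$warnings; io_72h <- st$value
    st <- try_stage(compute_io(activity, beds), warns, "io")
    warns <- st$warnings; io_full <- st$value
  } else warns <- c(warns, "io: no bed spans available")

  # spectral rhythm + r24, per signal
  rhythm_of <- function(series) {
    hourly <- aggregate_series(series, 60, "mean",
                               config$ingest$bin_missing_frac)
    r24 <- autocorr24(hourly)
    compl <- suppressWarnings(
      interpolate_missing(hourly, config$ingest$interp_warn_frac))
    spec <- periodogram(compl, config$spectral$period_grid)
    est <- dominant_rhythm(spec, config$spectral$n_resample,
                           config$spectral$n_scramble, seed = seed,
                           ci_level = config$spectral$ci_level)
    est$fraction_interpolated <- attr(compl, "fraction_interpolated")
    list(estimate = est, r24 = r24)
  }
  st <- try_stage(rhythm_of(activity), warns, "activity rhythm")
  warns <- st$warnings; act_rhythm <- st$value
  temp_rhythm <- NULL
  if (!is.null(temperature)) {
    st <- try_stage(rhythm_of(temperature), warns, "temperature rhythm")
    warns <- st$warnings; temp_rhythm <- st$value
  }

  # cosinor fits and temperature classification
  temp_cosinor <- temp_class <- NULL
  if (!is.null(temperature)) {
    st <- try_stage(fit_temperature_cosinor(temperature,
                                            config$cosinor$n_boot, seed),
                    warns, "temperature cosinor")
    warns <- st$warnings; temp_cosinor <- st$value
    if (!is.null(temp_cosinor) && !is.null(temp_rhythm))
      temp_class <- classify_temperature_rhythm(temp_rhythm$estimate,
                                                temp_cosinor)
  }
  cortisol_cosinor <- NULL
  if (!is.null(subject$cortisol)) {
    st <- try_stage(fit_cortisol_cosinor(subject$cortisol,
                                         config$cosinor$n_boot, seed),
                    warns, "cortisol cosinor")
    warns <- st$warnings; cortisol_cosinor <- st$value
  } else warns <- c(warns, "cortisol: panel absent")

  # DLMO
  dlmo <- NULL
  if (!is.null(subject$melatonin)) {
    validity <- if (!is.null(subject$light))
      check_dim_light(subject$light, subject$melatonin$times,
                      config$dlmo$lux_cutoff, config$dlmo$lux_spike_mult)
    else NULL
    ind <- individual_threshold(subject$melatonin, config$dlmo$rise_frac,
                                config$dlmo$baseline_cv_max)
    thr <- ind$threshold; src <- "individual"
    if (is.na(thr) && !is.null(pooled_melatonin_threshold)) {
      thr <- pooled_melatonin_threshold; src <- "pooled"
    }
    if (!is.na(thr)) {
      st <- try_stage(compute_dlmo(subject$melatonin, thr, validity, src),
                      warns, "dlmo")
      warns <- st$warnings; dlmo <- st$value
    } else warns <- c(warns, "dlmo: no baseline threshold available")
  } else warns <- c(warns, "melatonin: panel absent")

  covs <- subject$covariates
  structure(list(
    subject_id = if (!is.null(covs)) covs$subject_id[1] else NA_character_,
    covariates = covs, completeness = completeness,
    io_72h = io_72h, io_full = io_full,
    hmm_model = hmm$model, hmm_derived = hmm$derived,
    activity_rhythm = act_rhythm$estimate, activity_r24 = act_rhythm$r24,
    temperature_rhythm = temp_rhythm$estimate,
    temperature_r24 = temp_rhythm$r24,
    temp_cosinor = temp_cosinor, temp_class = temp_class,
    cortisol_cosinor = cortisol_cosinor, dlmo = dlmo,
    diary = subject$diary, melatonin = subject$melatonin,
    provenance = list(seed = seed, config = unclass(config)),
    warnings = warns), class = "subject_report")
}

num_or_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else
  as.numeric(x)

retiring_sd_h <- function(diary) {
  if (is.null(diary)) return(NA_real_)
  ax <- ifelse(diary$retiring >= 12, diary$retiring - 12,
               diary$retiring + 12)
  stats::sd(ax)
}

#' Per-subject covariate row from a report
#' @param rep a `subject_report`.
#' @return one-row data frame of the analysis outputs and covariates.
#' @export
report_row <- function(rep) {
  d <- rep$hmm_derived
  data.frame(
    subject_id = rep$subject_id,
    group = if (!is.null(rep$covariates)) rep$covariates$group else NA,
    phenotype = if (!is.null(rep$covariates$phenotype))
      rep$covariates$phenotype else NA,
    io_percent = num_or_na(rep$io_full$io_percent),
    io_72h = num_or_na(rep$io_72h$io_percent),
    category = if (!is.null(rep$io_72h)) rep$io_72h$category else NA,
    out_median = num_or_na(rep$io_full$out_median),
    p11 = num_or_na(d$p11), ri = num_or_na(d$ri),
    center_of_rest = num_or_na(d$center_of_rest),
    mid_MA = num_or_na(d$mid_MA), mid_HA = num_or_na(d$mid_HA),
    sleep_duration_sd = num_or_na(d$sleep_duration_sd),
    r24 = num_or_na(rep$activity_r24$r24),
    activity_amplitude = num_or_na(rep$activity_rhythm$amplitude),
    activity_acrophase = num_or_na(rep$activity_rhythm$acrophase),
    temp_amplitude = num_or_na(rep$temp_cosinor$amplitude[1]),
    temp_acrophase = num_or_na(rep$temp_cosinor$acrophase),
    temp_physiologic = if (!is.null(rep$temp_class))
      as.integer(rep$temp_class$label == "physiologic") else NA_integer_,
    cortisol_mesor = num_or_na(rep$cortisol_cosinor$mesor),
    cortisol_amplitude = num_or_na(rep$cortisol_cosinor$amplitude[1]),
    cortisol_acrophase = num_or_na(rep$cortisol_cosinor$acrophase),
    cortisol_significant = if (!is.null(rep$cortisol_cosinor))
      as.integer(rep$cortisol_cosinor$significant) else NA_integer_,
    dlmo_h = if (!is.null(rep$dlmo) && rep$dlmo$determined)
      rep$dlmo$dlmo_clock_h else NA_real_,
    retiring_sd = retiring_sd_h(rep$diary),
    exercise_days = if (!is.null(rep$covariates$exercise_days))
      rep$covariates$exercise_days else NA_integer_,
    age = if (!is.null(rep$covariates$age)) rep$covariates$age else NA,
    sex = if (!is.null(rep$covariates$sex)) rep$covariates$sex else NA,
    chronotype = if (!is.null(rep$covariates$chronotype))
      rep$covariates$chronotype else NA,
    completeness = rep$completeness,
    stringsAsFactors = FALSE)
}

#' Run the cohort-level analysis
#'
#' Analyzes each subject, applies group-pooled melatonin thresholds to
#' subjects lacking an individual baseline, assembles the covariate
#' table, and computes group contrasts (Welch/Fisher), the Spearman
#' correlation matrix of the four rest-activity circadian parameters
#' (I<O, P1-1, RI, r24), low/high classification counts and the AICc
#' determinant analysis of I<O.
#'
#' @param records list of subject records (or directory paths).
#' @param config a [circarest_config()].
#' @param determinant_candidates candidate predictors for the I<O model
#'   selection.
#' @return A `cohort_report` list with `subjects`, `table`,
#'   `pooled_thresholds`, `counts`, `contrasts`, `racr_correlation`,
#'   `determinants`, `warnings`.
#' @export
run_cohort <- function(records, config = circarest_config(),
                       determinant_candidates = c(
                         "activity_amplitude", "sleep_duration_sd",
                         "out_median", "mid_MA", "retiring_sd",
                         "exercise_days", "chronotype", "age")) {
  warns <- character(0)
  if (is.character(records)) records <- lapply(records, read_subject_dir)

  # group-pooled melatonin thresholds from subjects with an individual
  # baseline, one threshold per group
  groups <- vapply(records, function(r)
    if (!is.null(r$covariates)) as.character(r$covariates$group[1])
    else "unknown", character(1))
  pooled <- list()
  for (g in unique(groups)) {
    panels <- lapply(records[groups == g], `[[`, "melatonin")
    panels <- panels[!vapply(panels, is.null, logical(1))]
    pooled[[g]] <- tryCatch(
      pooled_threshold(panels, config$dlmo$rise_frac,
                       config$dlmo$baseline_cv_max)$threshold,
      error = function(e) NA_real_)
  }

  reports <- lapply(seq_along(records), function(i)
    run_subject(records[[i]], config,
                pooled_melatonin_threshold = pooled[[groups[i]]]))
  tab <- do.call(rbind, lapply(reports, report_row))

  # low/high classification counts per group
  counts <- table(group = tab$group, category = tab$category)

  # contrasts between the two I<O categories within patients, and
  # patients-high vs controls, for the main circadian parameters
  cont_vars <- c("io_percent", "p11", "ri", "r24", "mid_HA",
                 "activity_amplitude", "sleep_duration_sd",
                 "temp_amplitude", "cortisol_amplitude")
  pat <- tab[tab$group == "patient", ]
  ctl <- tab[tab$group == "control", ]
  contrast_set <- function(a, b) {
    out <- lapply(cont_vars, function(v) {
      x <- a[[v]]; y <- b[[v]]
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2)
        return(data.frame(variable = v, statistic = NA_real_,
                          p = NA_real_))
      gc <- group_compare(x, y, "welch")
      data.frame(variable = v, statistic = gc$statistic, p = gc$p)
    })
    do.call(rbind, out)
  }
  contrasts <- list()
  if (sum(pat$category == "low", na.rm = TRUE) >= 2 &&
      sum(pat$category == "high", na.rm = TRUE) >= 2) {
    contrasts$patients_low_vs_high <-
      contrast_set(pat[pat$category == "low", ],
                   pat[pat$category == "high", ])
  } else warns <- c(warns, "contrasts: too few patients per category")
  if (nrow(ctl) >= 2 && nrow(pat) >= 2)
    contrasts$patients_vs_controls <- contrast_set(pat, ctl)
  if (nrow(pat) && nrow(ctl)) {
    disrupt_tab <- rbind(
      patient = c(sum(pat$category == "low", na.rm = TRUE),
                  sum(pat$category == "high", na.rm = TRUE)),
      control = c(sum(ctl$category == "low", na.rm = TRUE),
                  sum(ctl$category == "high", na.rm = TRUE)))
    colnames(disrupt_tab) <- c("low", "high")
    contrasts$disruption_prevalence <-
      group_compare(disrupt_tab, kind = "fisher",
                    convention = config$determinants$fisher_convention)
  }

  racr <- tab[, c("io_percent", "p11", "ri", "r24")]
  racr_cor <- suppressWarnings(
    stats::cor(racr, use = "pairwise.complete.obs", method = "spearman"))

  det <- tryCatch(
    select_model(pat, "io_percent",
                 intersect(determinant_candidates, names(tab)),
                 include_intercept = TRUE,
                 max_predictors = config$determinants$max_predictors),
    error = function(e) {
      warns <<- c(warns, paste("determinants:", conditionMessage(e)))
      NULL
    })
  det_cor <- tryCatch(
    pairwise_correlations(pat, "io_percent",
                          intersect(determinant_candidates, names(tab))),
    error = function(e) NULL)

  structure(list(subjects = reports, table = tab,
                 pooled_thresholds = pooled, counts = counts,
                 contrasts = contrasts, racr_correlation = racr_cor,
                 determinants = det, determinant_correlations = det_cor,
                 provenance = list(seed = config$seed,
                                   config = unclass(config)),
                 warnings = warns),
            class = "cohort_report")
}

#' Write a cohort report as JSON
#'
#' Machine-readable summary (covariate table, counts, contrasts,
#' correlation matrix, determinant analysis); per-subject model objects
#' are reduced to their headline numbers.
#'
#' @param report a `cohort_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_json <- function(report, path) {
  out <- list(
    table = report$table,
    counts = as.data.frame(report$counts),
    contrasts = report$contrasts,
    racr_correlation = report$racr_correlation,
    determinants = if (!is.null(report$determinants)) list(
      selected = report$determinants$selected,
      coefficients = as.list(report$determinants$coefficients),
      adj_r_squared = report$determinants$adj_r_squared,
      aicc = report$determinants$aicc) else NULL,
    warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
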