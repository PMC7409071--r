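# Synthetic cohort generator: emulates one week of tele-monitored data per
# subject (minute activity counts and chest temperature, wrist light, daily
# diary, 2-day cortisol panel, evening melatonin panel) with robust vs
# disrupted circadian phenotypes.

# Evaluate `code` under a temporary RNG state so generators are pure
# functions of their seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Stable per-subject seed derived from a master seed; distinct master seeds
# give disjoint per-subject seed sets for cohorts of realistic size.
derive_seed <- function(master, idx) {
  as.integer((as.double(master) %% 2147483629 * 1000003 + idx * 7919) %%
               2147483629) + 1L
}

#' Ground-truth profile of a synthetic subject
#'
#' Collects every generative parameter for one subject: the 3-state
#' rest-activity chain (per-state lognormal minute counts plus a base 5-min
#' transition matrix tilted towards the rest state in bed and towards the
#' active states out of bed), the two-harmonic temperature rhythm, cortisol
#' and melatonin truths, diary timing means/SDs and exercise propensity.
#'
#' @param subject_id character id.
#' @param group `"patient"` or `"control"`.
#' @param phenotype `"robust"` or `"disrupted"`.
#' @param age,sex demographics (`sex` is `"M"` or `"F"`).
#' @param hmm_truth list with `meanlog`, `sdlog` (length-3, minute-count
#'   lognormal parameters for IA < MA < HA), `transition` (3x3
#'   row-stochastic base matrix at the 5-min step), `night_tilt`,
#'   `day_tilt` (log-scale multiplicative tilts applied in/out of bed).
#' @param temp_truth list with `mesor`, `amp24`, `acro24`, `amp12`,
#'   `acro12`, `ar_phi`, `ar_sd` (degrees C; acrophases in clock hours).
#' @param cortisol_truth list with `mesor`, `amplitude`, `acrophase`,
#'   `noise_sd` (nmol/L).
#' @param melatonin_truth list with `baseline` (pg/mL), `onset` (clock h),
#'   `rise_scale` (logistic scale, h; midpoint is `onset + 0.5`), `fold`
#'   (evening rise as a multiple of baseline), `cv` (measurement CV).
#' @param diary_truth list with `retiring_mean`, `retiring_sd`,
#'   `rising_mean`, `rising_sd` (clock h / h).
#' @param exercise_propensity probability per day of an exercise span.
#' @param covariates named list of additional numeric covariates
#'   (chronotype score, questionnaire scores).
#' @param seed integer seed controlling everything generated from this
#'   profile.
#' @return A validated `subject_profile` object.
#' @export
subject_profile <- function(subject_id, group, phenotype, age, sex,
                            hmm_truth, temp_truth, cortisol_truth,
                            melatonin_truth, diary_truth,
                            exercise_propensity, covariates = list(),
                            seed = 1L) {
  group <- match.arg(group, c("patient", "control"))
  phenotype <- match.arg(phenotype, c("robust", "disrupted"))
  sex <- match.arg(sex, c("M", "F"))
  P <- hmm_truth$transition
  stopifnot(is.matrix(P), dim(P) == c(3, 3))
  if (any(P < 0 | P > 1)) stop("transition probabilities must lie in [0,1]")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (any(c(temp_truth$amp24, temp_truth$amp12, cortisol_truth$amplitude) < 0))
    stop("amplitudes must be non-negative")
  for (a in c(temp_truth$acro24, temp_truth$acro12, cortisol_truth$acrophase))
    if (a < 0 || a >= 24) stop("acrophases must lie in [0, 24)")
  structure(list(subject_id = subject_id, group = group,
                 phenotype = phenotype, age = age, sex = sex,
                 hmm_truth = hmm_truth, temp_truth = temp_truth,
                 cortisol_truth = cortisol_truth,
                 melatonin_truth = melatonin_truth,
                 diary_truth = diary_truth,
                 exercise_propensity = exercise_propensity,
                 covariates = covariates, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Default phenotype parameter sets
#'
#' Draws a subject-level profile around the frozen phenotype defaults.
#' Robust subjects have consolidated nocturnal rest (strong in-bed tilt
#' towards the IA state), a high-amplitude nocturnal temperature rhythm and
#' regular diaries; disrupted subjects have fragmented rest, damped and
#' phase-scattered temperature rhythms, irregular diaries and low exercise
#' propensity.
#'
#' @inheritParams subject_profile
#' @return A `subject_profile`.
#' @export
default_subject_profile <- function(subject_id, group = "patient",
                                    phenotype = "robust", seed = 1L) {
  phenotype <- match.arg(phenotype, c("robust", "disrupted"))
  group <- match.arg(group, c("patient", "control"))
  with_seed(seed * 5 + 11, {
    robust <- phenotype == "robust"
    base_P <- matrix(c(0.95, 0.045, 0.005,
                       0.05, 0.90,  0.05,
                       0.02, 0.18,  0.80), 3, 3, byrow = TRUE)
    hmm_truth <- list(
      meanlog = c(if (robust) -0.5 else -0.3,
                  rnorm(1, if (robust) 4.7 else 4.4, 0.15),
                  rnorm(1, if (robust) 5.8 else 5.5, 0.15)),
      sdlog = if (robust) c(1.0, 0.5, 0.4) else c(1.1, 0.6, 0.5),
      transition = base_P,
      night_tilt = max(0.5, rnorm(1, if (robust) 4.0 else 1.2,
                                  if (robust) 0.4 else 0.2)),
      day_tilt = max(0.2, rnorm(1, if (robust) 1.5 else 0.8, 0.2)))
    temp_truth <- list(
      mesor = rnorm(1, 36.2, 0.2),
      amp24 = if (robust) max(0.3, rnorm(1, 0.55, 0.08))
              else max(0.03, rnorm(1, 0.16, 0.06)),
      acro24 = if (robust) (2.5 + rnorm(1, 0, 1.2)) %% 24 else runif(1, 0, 24),
      amp12 = if (robust) runif(1, 0.1, 0.2) else runif(1, 0.02, 0.08),
      acro12 = runif(1, 0, 12),
      ar_phi = 0.95, ar_sd = 0.04)
    cortisol_truth <- list(
      mesor = max(3, rnorm(1, 8, 1.5)),
      amplitude = if (robust) max(1, rnorm(1, 6, 1.2))
                  else max(0.5, rnorm(1, 4, 1.5)),
      acrophase = rnorm(1, 8.5, 1) %% 24,
      noise_sd = if (robust) 1.2 else 2.0)
    onset_mean <- if (group == "patient") {
      if (robust) 21.7 else 19.8
    } else if (robust) 20.5 else 19.9
    melatonin_truth <- list(
      baseline = max(1, rnorm(1, if (group == "patient") 3.2 else 2.3, 0.5)),
      onset = min(23, max(19.3, rnorm(1, onset_mean, 0.55))),
      rise_scale = 0.02,
      fold = if (group == "control") 6 else if (robust) 5 else 3,
      cv = 0.08)
    diary_truth <- list(
      retiring_mean = rnorm(1, 23.0, 0.5) %% 24,
      retiring_sd = if (robust) max(0.1, rnorm(1, 0.3, 0.08))
                    else max(0.5, rnorm(1, 1.1, 0.2)),
      rising_mean = rnorm(1, 7.2, 0.5),
      rising_sd = if (robust) max(0.1, rnorm(1, 0.35, 0.1))
                  else max(0.5, rnorm(1, 1.2, 0.2)))
    age <- if (group == "patient") round(min(82, max(40, rnorm(1, 66, 9))))
           else round(min(80, max(18, rnorm(1, 50, 14))))
    sex <- if (runif(1) < (if (group == "patient") 0.84 else 0.5)) "M" else "F"
    covs <- list(
      chronotype = round(rnorm(1, 58, 8)),
      psqi = round(max(0, rnorm(1, if (robust) 4.5 else 6.5, 2))),
      hads = round(max(0, rnorm(1, if (robust) 5 else 7, 3))),
      mdasi_sleep = round(max(0, rnorm(1, if (robust) 1.5 else 3, 1.2)), 1))
    subject_profile(subject_id, group, phenotype, age, sex, hmm_truth,
                    temp_truth, cortisol_truth, melatonin_truth, diary_truth,
                    exercise_propensity = if (robust) 0.7 else 0.15,
                    covariates = covs, seed = seed)
  })
}

# In-bed indicator for a vector of absolute times given bed spans.
in_bed_flag <- function(times, beds) {
  flag <- rep(FALSE, length(times))
  for (i in seq_len(nrow(beds)))
    flag <- flag | (times >= beds$bed_start[i] & times < beds$bed_end[i])
  flag
}

#' Generate one synthetic subject record
#'
#' Simulates the full measurement set for one subject: a diary, a 3-state
#' rest-activity chain at the 5-min step (transition rows tilted towards IA
#' in bed and towards MA/HA out of bed during the diurnal span) expanded to
#' minute-level lognormal counts, a two-harmonic temperature rhythm with
#' AR(1) noise, a light series dim after 19:00, a 12-sample cortisol panel
#' over two days at 3-h daytime spacing, and a 6-sample hourly evening
#' melatonin panel starting at 19:00.
#'
#' @param profile a [subject_profile()].
#' @param days recording length in days (>= 3).
#' @param start `POSIXct` recording start (default noon, so study days are
#'   noon-to-noon).
#' @return A `synthetic_record` list with elements `activity`,
#'   `temperature`, `light`, `diary`, `cortisol`, `melatonin`,
#'   `covariates` (one-row data frame) and `truth` (the profile).
#' @export
generate_subject <- function(profile, days = 7,
                             start = as.POSIXct("2020-01-06 12:00:00",
                                                tz = "UTC")) {
  stopifnot(inherits(profile, "subject_profile"))
  if (days < 3) stop("days must be >= 3: 72-h classification impossible")
  if (all(profile$hmm_truth$sdlog <= 0))
    stop("degenerate truth: all states have zero-variance emissions")
  with_seed(profile$seed * 13 + 1, {
    n_min <- days * 1440
    times <- start + (seq_len(n_min) - 1) * 60
    dt <- profile$diary_truth

    # diary
    retiring <- (rnorm(days, dt$retiring_mean, dt$retiring_sd)) %% 24
    rising <- pmin(11.5, pmax(4.5, rnorm(days, dt$rising_mean, dt$rising_sd)))
    ret_ax <- ifelse(retiring >= 12, retiring - 12, retiring + 12)
    # keep retiring on the evening side and at least 1 h before rising
    ret_ax <- pmax(8.5, pmin(ret_ax, rising + 12 - 1))
    retiring <- (ret_ax + 12) %% 24
    exercise <- lapply(seq_len(days), function(d) {
      if (runif(1) < profile$exercise_propensity) {
        s <- runif(1, 14, 18); len <- runif(1, 0.5, 1)
        matrix(c(s, s + len), 1, 2)
      } else NULL
    })
    meals <- lapply(seq_len(days), function(d)
      sort((c(8, 12.5, 19) + rnorm(3, 0, 0.3)) %% 24))
    diary <- diary_log(seq_len(days), retiring, rising, exercise, meals)
    beds <- bed_spans(diary, start)

    # 5-min state chain with bed/day multiplicative tilt
    ht <- profile$hmm_truth
    n_bin <- days * 288
    bin_times <- start + (seq_len(n_bin) - 1) * 300
    bed_bin <- in_bed_flag(bin_times, beds)
    states <- integer(n_bin)
    states[1] <- if (bed_bin[1]) 1L else 2L
    tilt <- function(bed) {
      w <- if (bed) c(exp(ht$night_tilt), 1, 1)
           else c(1, exp(ht$day_tilt), exp(ht$day_tilt))
      Pt <- sweep(ht$transition, 2, w, `*`)
      Pt / rowSums(Pt)
    }
    P_bed <- tilt(TRUE); P_day <- tilt(FALSE)
    u <- runif(n_bin)
    for (t in 2:n_bin) {
      p <- if (bed_bin[t]) P_bed[states[t - 1], ] else P_day[states[t - 1], ]
      states[t] <- findInterval(u[t], cumsum(p)) + 1L
      if (states[t] > 3L) states[t] <- 3L
    }

    # minute counts
    st_min <- rep(states, each = 5)
    counts <- round(rlnorm(n_min, ht$meanlog[st_min], ht$sdlog[st_min]))
    activity <- activity_series(start, counts)

    # temperature: two-harmonic rhythm + AR(1) noise
    tt <- profile$temp_truth
    h <- clock_hours(times)
    mu <- tt$mesor + tt$amp24 * cos(2 * pi * (h - tt$acro24) / 24) +
      tt$amp12 * cos(2 * pi * (h - tt$acro12) / 12)
    noise <- as.numeric(stats::filter(rnorm(n_min, 0, tt$ar_sd), tt$ar_phi,
                                      method = "recursive"))
    temperature <- temperature_series(start, mu + noise)

    # light: bright by day, dim after 19:00, dark in bed
    bed_min <- in_bed_flag(times, beds)
    lux <- numeric(n_min)
    day_min <- !bed_min & h >= 7 & h < 19
    eve_min <- !bed_min & !day_min
    lux[day_min] <- rlnorm(sum(day_min), log(300), 0.8)
    lux[eve_min] <- runif(sum(eve_min), 2, 30)
    lux[bed_min] <- runif(sum(bed_min), 0, 1)
    light <- light_series(start, lux)

    # cortisol: 12 samples, 3-h daytime spacing over study days 2-3
    ct <- profile$cortisol_truth
    c_times <- as.POSIXct(character(0), tz = "UTC")
    for (d in 2:3) {
      day0 <- start + (d - 1) * 86400          # noon of study day d
      rise_h <- diary$rising[min(d, days)]
      c_times <- c(c_times, day0 + (rise_h - 12 + 24 + 0.25 + 3 *
                                      (0:5)) * 3600)
    }
    c_h <- clock_hours(c_times)
    c_conc <- pmax(0.1, ct$mesor +
                     ct$amplitude * cos(2 * pi * (c_h - ct$acrophase) / 24) +
                     rnorm(length(c_h), 0, ct$noise_sd))
    cortisol <- saliva_panel("cortisol", c_times, c_conc)

    # melatonin: 6 hourly samples from 19:00 on study day 3
    mt <- profile$melatonin_truth
    eve0 <- start + 2 * 86400 + 7 * 3600      # 19:00 of study day 3
    m_times <- eve0 + (0:5) * 3600
    m_h <- 19 + (0:5)
    m_mu <- mt$baseline + mt$fold * mt$baseline *
      stats::plogis((m_h - (mt$onset + 0.5)) / mt$rise_scale)
    m_conc <- m_mu * exp(rnorm(6, 0, mt$cv))
    melatonin <- saliva_panel("melatonin", m_times, m_conc)

    covariates <- data.frame(
      subject_id = profile$subject_id, group = profile$group,
      phenotype = profile$phenotype, age = profile$age, sex = profile$sex,
      exercise_days = sum(!vapply(exercise, is.null, logical(1))),
      stringsAsFactors = FALSE)
    for (nm in names(profile$covariates))
      covariates[[nm]] <- profile$covariates[[nm]]

    structure(list(activity = activity, temperature = temperature,
                   light = light, diary = diary, cortisol = cortisol,
                   melatonin = melatonin, covariates = covariates,
                   truth = profile),
              class = "synthetic_record")
  })
}

#' Simulate 5-min binned activity directly from a 3-state chain
#'
#' Bin-level generator whose emission family matches the fitted model
#' exactly (Gaussian on the log(count + 1) scale), so parameter-recovery
#' checks have a well-defined truth.
#'
#' @param truth list with `mu`, `sigma` (length-3 emission location/SD on
#'   the log(count+1) scale), `transition` (3x3 row-stochastic), optional
#'   `init` (initial distribution; default stationary-ish uniform).
#' @param n_bins number of 5-min bins to draw.
#' @param seed integer seed.
#' @return list with `counts` (acc/min scale) and `states`.
#' @export
simulate_hmm_bins <- function(truth, n_bins, seed = 1L) {
  stopifnot(all(abs(rowSums(truth$transition) - 1) < 1e-9))
  with_seed(seed, {
    init <- truth$init %||% rep(1 / 3, 3)
    s <- integer(n_bins)
    s[1] <- sample.int(3, 1, prob = init)
    u <- runif(n_bins)
    cp <- apply(truth$transition, 1, cumsum)   # 3 x 3, columns = from-state
    for (t in 2:n_bins)
      s[t] <- findInterval(u[t], cp[, s[t - 1]]) + 1L
    y <- pmax(0, exp(rnorm(n_bins, truth$mu[s], truth$sigma[s])) - 1)
    list(counts = y, states = s)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference 3-state truth for parameter-recovery studies
#'
#' A fixed, well-identified truth for [simulate_hmm_bins()]: emission
#' locations separated by several SDs and transition probabilities chosen
#' so each state is visited often enough over a 7-day series that the
#' empirical transition SE sits well below the recovery tolerance.
#'
#' @return list with `mu`, `sigma`, `transition`.
#' @export
example_hmm_truth <- function() {
  list(mu = c(0.7, 4.0, 5.9), sigma = c(0.4, 0.5, 0.45),
       transition = matrix(c(0.95, 0.04, 0.01,
                             0.05, 0.90, 0.05,
                             0.02, 0.08, 0.90), 3, 3, byrow = TRUE))
}

#' Generate a synthetic cohort
#'
#' @param spec named list with elements `patients` and/or `controls`, each
#'   a named count vector over phenotypes, e.g.
#'   `list(patients = c(disrupted = 13, robust = 12),
#'         controls = c(disrupted = 4, robust = 29))`.
#' @param seed master seed; per-subject seeds are derived deterministically
#'   from it.
#' @param days recording length per subject.
#' @param missing_events_per_day rate of off-body (shower) spans injected
#'   per day; 0 disables injection.
#' @return list with `records` (list of `synthetic_record`) and
#'   `covariates` (one row per subject).
#' @export
generate_cohort <- function(spec, seed = 1L, days = 7,
                            missing_events_per_day = 1) {
  counts <- list(patient = spec$patients, control = spec$controls)
  total <- sum(unlist(counts))
  if (is.null(total) || total == 0) {
    warning("zero subjects requested; returning empty cohort")
    return(list(records = list(), covariates = data.frame()))
  }
  records <- vector("list", total)
  idx <- 0L
  for (group in names(counts)) {
    for (ph in names(counts[[group]])) {
      for (k in seq_len(counts[[group]][[ph]])) {
        idx <- idx + 1L
        sid <- sprintf("%s_%s_%02d", substr(group, 1, 3), substr(ph, 1, 3), k)
        prof <- default_subject_profile(sid, group, ph,
                                        seed = derive_seed(seed, idx))
        rec <- generate_subject(prof, days = days)
        if (missing_events_per_day > 0)
          rec <- inject_missingness(rec, missing_events_per_day)
        records[[idx]] <- rec
      }
    }
  }
  covariates <- do.call(rbind, lapply(records, `[[`, "covariates"))
  list(records = records, covariates = covariates)
}

#' Inject off-body (shower) spans into a record
#'
#' Inserts spans of 10-40 min during which the chest sensor is off-body:
#' temperature decays exponentially towards room temperature and activity
#' is masked as missing. The true injected-minute mask is retained in
#' `record$injected_mask` for validating downstream span detection.
#'
#' @param record a `synthetic_record`.
#' @param events_per_day span rate per day (count is `round(rate * days)`).
#' @param spans optional explicit spans as a matrix with columns
#'   `start_min` (1-based minute index) and `len_min`, overriding random
#'   placement.
#' @param room_temp_c ambient temperature the sensor decays towards.
#' @param tau_min exponential decay time constant in minutes.
#' @return The modified record.
#' @export
inject_missingness <- function(record, events_per_day, spans = NULL,
                               room_temp_c = 21, tau_min = 1.5) {
  if (events_per_day < 0) stop("rate must be >= 0")
  n <- length(record$activity)
  days <- n / 1440
  if (is.null(spans)) {
    n_ev <- round(events_per_day * days)
    if (n_ev == 0) {
      record$injected_mask <- record$injected_mask %||% rep(FALSE, n)
      return(record)
    }
    spans <- with_seed(record$truth$seed * 31 + 7, {
      out <- matrix(NA_real_, n_ev, 2)
      occupied <- rep(FALSE, n)
      for (i in seq_len(n_ev)) {
        repeat {
          len <- round(runif(1, 10, 40))
          s <- sample.int(n - len, 1)
          if (!any(occupied[s:(s + len - 1)])) break
        }
        occupied[s:(s + len - 1)] <- TRUE
        out[i, ] <- c(s, len)
      }
      out
    })
  }
  total_len <- sum(spans[, 2])
  if (total_len > 0.5 * n)
    stop("requested missingness would remove more than 50% of the data")
  injected <- record$injected_mask %||% rep(FALSE, n)
  temp <- record$temperature$values
  act_missing <- record$activity$missing
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, 1]; len <- spans[i, 2]
    j <- s:min(n, s + len - 1)
    t0 <- if (s > 1 && !is.na(temp[s - 1])) temp[s - 1] else 36
    temp[j] <- room_temp_c + (t0 - room_temp_c) * exp(-(seq_along(j)) / tau_min)
    act_missing[j] <- TRUE
    injected[j] <- TRUE
  }
  record$temperature <- temperature_series(record$temperature$start, temp)
  av <- record$activity$values
  av[act_missing] <- NA_real_
  record$activity <- activity_series(record$activity$start, av, act_missing)
  record$injected_mask <- injected
  record
}
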