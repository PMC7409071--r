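# 3-state hidden Markov model of 5-min rest-activity: Gaussian emissions on
# the log(count+1) scale, states ordered IA < MA < HA by emission location,
# optional circadian (two-harmonic) modulation of the transition logits.
# Derived quantifiers: P1-1, rhythm index, center-of-rest, state mid-levels,
# per-day sleep windows and sleep-duration variability.

hmm_state_labels <- c("IA", "MA", "HA")

# harmonic basis (sin/cos of 24-h and 12-h components) at clock hours h
harmonic_basis <- function(h) {
  cbind(sin(2 * pi * h / 24), cos(2 * pi * h / 24),
        sin(2 * pi * h / 12), cos(2 * pi * h / 12))
}

# K x K transition matrices at each of the given clock hours; returns the
# flattened (T x K x K) cube hmm_forward_backward expects.
transition_cube <- function(model, h) {
  K <- model$n_states
  Tn <- length(h)
  if (is.null(model$harmonic)) {
    lA <- log(pmax(model$transition, 1e-300))
    cube <- numeric(Tn * K * K)
    for (i in seq_len(K)) for (j in seq_len(K))
      cube[(1:Tn) + Tn * ((i - 1) + K * (j - 1))] <- lA[i, j]
    return(cube)
  }
  X <- cbind(1, harmonic_basis(h))           # T x 5
  cube <- numeric(Tn * K * K)
  for (i in seq_len(K)) {
    eta <- X %*% model$harmonic[[i]]         # T x K, reference col i is 0
    lse <- log(rowSums(exp(eta - apply(eta, 1, max)))) + apply(eta, 1, max)
    lp <- eta - lse
    for (j in seq_len(K))
      cube[(1:Tn) + Tn * ((i - 1) + K * (j - 1))] <- lp[, j]
  }
  cube
}

#' Transition matrix at a clock time
#' @param model a fitted `hmm_model`.
#' @param clock_h clock hour(s) in `[0, 24)`.
#' @return For one time, a K x K matrix; for several, a list of matrices.
#' @export
transition_at <- function(model, clock_h) {
  K <- model$n_states
  cube <- transition_cube(model, clock_h)
  Tn <- length(clock_h)
  out <- lapply(seq_len(Tn), function(t) {
    m <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      m[i, j] <- exp(cube[t + Tn * ((i - 1) + K * (j - 1))])
    dimnames(m) <- list(hmm_state_labels[1:K], hmm_state_labels[1:K])
    m
  })
  if (Tn == 1) out[[1]] else out
}

emission_loglik <- function(y, miss, mu, sigma) {
  K <- length(mu)
  logB <- matrix(0, length(y), K)
  ok <- !miss
  for (k in seq_len(K))
    logB[ok, k] <- stats::dnorm(y[ok], mu[k], sigma[k], log = TRUE)
  logB
}

# one EM run from a given start; homogeneous or harmonic transitions
em_run <- function(y, miss, h, K, mu, sigma, max_iter, tol,
                   harmonic = FALSE) {
  Tn <- length(y)
  A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9
  pi0 <- rep(1 / K, K)
  coefs <- NULL
  X <- if (harmonic) cbind(1, harmonic_basis(h[-Tn])) else NULL
  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- emission_loglik(y, miss, mu, sigma)
    cube <- if (harmonic) {
      m <- list(n_states = K, harmonic = coefs)
      if (is.null(coefs)) m$harmonic <- lapply(seq_len(K), function(i) {
        cf <- matrix(0, 5, K)
        cf[1, ] <- log(pmax(A[i, ], 1e-12) / max(A[i, i], 1e-12))
        cf[1, i] <- 0
        cf
      })
      coefs <- m$harmonic
      transition_cube(m, h[-Tn])
    } else transition_cube(list(n_states = K, transition = A,
                                harmonic = NULL), h[seq_len(Tn - 1)])
    es <- hmm_forward_backward(logB, log(pi0), cube)
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    gamma <- es$gamma
    xi <- array(es$xi, dim = c(Tn - 1, K, K))
    # M-step: emissions
    ok <- !miss
    for (k in seq_len(K)) {
      w <- gamma[ok, k]
      sw <- sum(w)
      if (sw > 1e-10) {
        mu[k] <- sum(w * y[ok]) / sw
        # SD floor (log scale) guards against singular components at
        # repeated values such as all-zero bins
        sigma[k] <- sqrt(max(sum(w * (y[ok] - mu[k])^2) / sw, 2.5e-3))
      }
    }
    pi0 <- pmax(gamma[1, ], 1e-10); pi0 <- pi0 / sum(pi0)
    # M-step: transitions
    if (!harmonic) {
      num <- apply(xi, c(2, 3), sum)
      A <- num / pmax(rowSums(num), 1e-300)
      A <- pmax(A, 1e-12); A <- A / rowSums(A)
    } else {
      coefs <- lapply(seq_len(K), function(i) {
        W <- xi[, i, ]                       # (T-1) x K
        fit_row_logit(X, W, coefs[[i]], ref = i)
      })
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (harmonic) {
    # time-averaged transition matrix over the 24-h clock for reporting
    hh <- seq(0, 24, length.out = 97)[-97]
    mats <- transition_at(list(n_states = K, harmonic = coefs), hh)
    A <- Reduce(`+`, mats) / length(mats)
  }
  list(mu = mu, sigma = sigma, transition = A, init = pi0,
       harmonic = if (harmonic) coefs else NULL, loglik = ll_old,
       ll_trace = ll_trace, converged = converged)
}

# weighted multinomial-logit M-step for one transition row: maximize
# sum_t sum_j W[t,j] log softmax_j(X theta_j), reference category `ref`.
fit_row_logit <- function(X, W, cf, ref) {
  K <- ncol(W); p <- ncol(X)
  free <- setdiff(seq_len(K), ref)
  par0 <- as.vector(cf[, free])
  obj <- function(par) {
    cf[, free] <- matrix(par, p, length(free))
    eta <- X %*% cf
    m <- apply(eta, 1, max)
    lse <- m + log(rowSums(exp(eta - m)))
    -sum(W * (eta - lse))
  }
  gr <- function(par) {
    cf[, free] <- matrix(par, p, length(free))
    eta <- X %*% cf
    m <- apply(eta, 1, max)
    P <- exp(eta - m); P <- P / rowSums(P)
    wt <- rowSums(W)
    G <- t(X) %*% (wt * P - W)               # p x K
    as.vector(G[, free])
  }
  o <- stats::optim(par0, obj, gr, method = "BFGS",
                    control = list(maxit = 50))
  cf[, free] <- matrix(o$par, p, length(free))
  cf[, ref] <- 0
  cf
}

#' Fit the rest-activity hidden Markov model
#'
#' EM fit of a K-state Gaussian HMM on log(count + 1) of 5-min aggregated
#' activity. Several restarts with quantile-based emission initialisation
#' are run and the best log-likelihood kept; states are relabelled by
#' ascending emission location (IA < MA < HA). With `harmonic = TRUE` the
#' transition logits are modulated by the first two harmonics of the 24-h
#' clock (multinomial-logit parameterisation), so rows remain stochastic
#' at every clock time.
#'
#' @param activity_5min a `binned_series` of 5-min mean activity (acc/min)
#'   or a numeric count vector (then `times` taken as a 5-min grid).
#' @param harmonic modulate transitions by time of day.
#' @param seed integer seed for the restarts.
#' @param n_states number of states (3 by default).
#' @param n_restarts,max_iter,tol EM controls.
#' @param degenerate_frac a state holding less posterior mass than this
#'   triggers a 2-state refit with `degenerate = TRUE`.
#' @return An `hmm_model`: emission locations `mu` and SDs `sigma` (on the
#'   log scale), `transition` (time-averaged under `harmonic`),
#'   `harmonic` coefficients or `NULL`, `loglik`, `converged`,
#'   `degenerate`, plus the data binning metadata.
#' @export
fit_hmm <- function(activity_5min, harmonic = FALSE, seed = 1L,
                    n_states = 3L, n_restarts = 5L, max_iter = 500L,
                    tol = 1e-6, degenerate_frac = 0.01) {
  if (is.numeric(activity_5min)) {
    activity_5min <- structure(
      list(kind = "activity",
           start = as.POSIXct("2020-01-06 12:00:00", tz = "UTC"),
           step = 300, values = activity_5min,
           missing = is.na(activity_5min)),
      class = "binned_series")
  }
  stopifnot(activity_5min$step == 300)
  y_raw <- activity_5min$values
  miss <- activity_5min$missing | is.na(y_raw)
  if (sum(!miss) < 288)
    stop("need at least 288 non-missing 5-min bins (1 day)")
  if (any(y_raw[!miss] < 0)) stop("activity counts must be non-negative")
  y <- log(ifelse(miss, 0, y_raw) + 1)
  h <- clock_hours(series_times(activity_5min))
  K <- as.integer(n_states)

  run_once <- function(K) {
    best <- NULL
    yok <- y[!miss]
    for (r in seq_len(n_restarts)) {
      # restart 1: evenly spaced quantiles; later restarts: random
      # centres drawn from the data, for init diversity
      mu0 <- with_seed(seed * 1000 + r, {
        if (r == 1) stats::quantile(yok, (1:K) / (K + 1), names = FALSE)
        else sample(yok, K)
      })
      sigma0 <- rep(max(stats::sd(yok) / 2, 0.1), K)
      fit <- em_run(y, miss, h, K, sort(mu0), sigma0, max_iter, tol,
                    harmonic = harmonic)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  }

  best <- run_once(K)
  # relabel by ascending emission location
  ord <- order(best$mu)
  best <- relabel_fit(best, ord, K)
  # degenerate-state check on posterior occupancy of the best fit
  model <- build_model(best, K, activity_5min, harmonic)
  occ <- state_occupancy(model, y, miss, h)
  degenerate <- FALSE
  # a state is degenerate when it holds almost no posterior mass or has
  # collapsed onto a neighbour's emission location
  if (K > 2 && (any(occ < degenerate_frac) || any(diff(best$mu) < 0.05))) {
    degenerate <- TRUE
    K <- 2L
    best <- run_once(K)
    best <- relabel_fit(best, order(best$mu), K)
    model <- build_model(best, K, activity_5min, harmonic)
  }
  model$degenerate <- degenerate
  model
}

relabel_fit <- function(fit, ord, K) {
  fit$mu <- fit$mu[ord]; fit$sigma <- fit$sigma[ord]
  fit$init <- fit$init[ord]
  fit$transition <- fit$transition[ord, ord, drop = FALSE]
  if (!is.null(fit$harmonic)) {
    # permute rows (list index) and target columns; re-zero the reference
    fit$harmonic <- lapply(seq_len(K), function(i) {
      cf <- fit$harmonic[[ord[i]]][, ord, drop = FALSE]
      sweep(cf, 1, cf[, i], `-`)
    })
  }
  fit
}

build_model <- function(fit, K, binned, harmonic) {
  structure(list(n_states = K, labels = hmm_state_labels[seq_len(K)],
                 mu = fit$mu, sigma = fit$sigma,
                 transition = fit$transition, init = fit$init,
                 harmonic = fit$harmonic, loglik = fit$loglik,
                 ll_trace = fit$ll_trace, converged = fit$converged,
                 bin_min = binned$step / 60, start = binned$start,
                 n_bins = length(binned$values)),
            class = "hmm_model")
}

state_occupancy <- function(model, y, miss, h) {
  logB <- emission_loglik(y, miss, model$mu, model$sigma)
  cube <- transition_cube(model, h[seq_len(length(y) - 1)])
  es <- hmm_forward_backward(logB, log(model$init), cube)
  colMeans(es$gamma)
}

#' Decode hidden states
#'
#' Global (Viterbi) decoding for the most-likely path plus per-bin
#' posterior state probabilities from the forward-backward recursion.
#' Missing bins carry no emission term, so their posteriors are propagated
#' through the chain.
#'
#' @param model a fitted `hmm_model`.
#' @param activity_5min the 5-min binned series the model was fitted on
#'   (or compatible).
#' @return An `hmm_decoding`: `path` (integer states), `posteriors`
#'   (T x K), `times`, `missing`, `counts`.
#' @export
decode_states <- function(model, activity_5min) {
  if (is.numeric(activity_5min)) {
    activity_5min <- structure(
      list(kind = "activity", start = model$start, step = 300,
           values = activity_5min, missing = is.na(activity_5min)),
      class = "binned_series")
  }
  if (activity_5min$step / 60 != model$bin_min)
    stop("series binning does not match the fitted model")
  y_raw <- activity_5min$values
  miss <- activity_5min$missing | is.na(y_raw)
  y <- log(ifelse(miss, 0, y_raw) + 1)
  h <- clock_hours(series_times(activity_5min))
  logB <- emission_loglik(y, miss, model$mu, model$sigma)
  if (length(y) == 1) {
    # stationary-weighted emission likelihood
    lp <- log(model$init) + logB[1, ]
    post <- exp(lp - max(lp)); post <- post / sum(post)
    return(structure(list(path = which.max(lp),
                          posteriors = matrix(post, 1),
                          times = series_times(activity_5min),
                          missing = miss, counts = y_raw,
                          loglik = log(sum(exp(lp - max(lp)))) + max(lp)),
                     class = "hmm_decoding"))
  }
  cube <- transition_cube(model, h[seq_len(length(y) - 1)])
  es <- hmm_forward_backward(logB, log(model$init), cube)
  path <- hmm_viterbi(logB, log(model$init), cube)
  structure(list(path = as.integer(path), posteriors = es$gamma,
                 times = series_times(activity_5min), missing = miss,
                 counts = y_raw, loglik = es$loglik),
            class = "hmm_decoding")
}

#' Derived circadian quantifiers from a fitted HMM
#'
#' * `mid_MA`, `mid_HA`: back-transformed emission locations (acc/min).
#' * `p11`: probability of staying in the IA state (time-average of the
#'   clock-varying entry under a harmonic model; the raw entry is reported
#'   as `p11_matrix`).
#' * `ri`: rhythm index in `[0, 1]` — mean Jaccard overlap of the
#'   IA-decoded clock-grid bin sets across all day pairs, weighted by the
#'   mean IA posterior of IA-decoded bins (definition
#'   `"jaccard-posterior-v1"`): 1 for identical fully-certain daily rest
#'   blocks, near 0 for unstructured paths.
#' * `center_of_rest`: circular mean clock time of IA bins weighted by IA
#'   posterior.
#'
#' @param model a fitted `hmm_model`.
#' @param decoding the matching [decode_states()] result.
#' @return An `hmm_derived` list; `ri`/`center_of_rest` are `NA` when no
#'   IA bins were decoded.
#' @export
derive_metrics <- function(model, decoding) {
  K <- model$n_states
  mid <- exp(model$mu) - 1
  p11_matrix <- model$transition[1, 1]
  p11 <- if (is.null(model$harmonic)) p11_matrix else {
    hh <- seq(0, 24, length.out = 241)[-241]
    mean(vapply(transition_at(model, hh), function(m) m[1, 1], numeric(1)))
  }
  ia <- decoding$path == 1L & !decoding$missing
  if (!any(ia)) {
    ri <- NA_real_; cor_time <- NA_real_
  } else {
    h <- clock_hours(decoding$times)
    day <- study_day(decoding$times, decoding$times[1])
    slot <- floor(((h - 12) %% 24) * 60 / model$bin_min)
    days <- sort(unique(day))
    sets <- lapply(days, function(d) unique(slot[ia & day == d]))
    if (length(days) < 2) ri <- NA_real_ else {
      pairs <- utils::combn(length(days), 2)
      jac <- apply(pairs, 2, function(p) {
        a <- sets[[p[1]]]; b <- sets[[p[2]]]
        u <- length(union(a, b))
        if (u == 0) 0 else length(intersect(a, b)) / u
      })
      w_post <- mean(decoding$posteriors[ia, 1])
      ri <- mean(jac) * w_post
    }
    cor_time <- circular_mean_hours(h[ia], decoding$posteriors[ia, 1])
  }
  sw <- estimate_sleep_windows(decoding)
  structure(list(mid_MA = if (K >= 2) mid[2] else NA_real_,
                 mid_HA = if (K >= 3) mid[3] else NA_real_,
                 p11 = p11, p11_matrix = p11_matrix, ri = ri,
                 ri_definition = "jaccard-posterior-v1",
                 center_of_rest = cor_time,
                 sleep_windows = sw$windows,
                 sleep_duration_sd = sw$sleep_duration_sd,
                 days_without_rest = sw$days_without_rest),
            class = "hmm_derived")
}

#' Per-day sleep windows from the decoded path
#'
#' For each noon-to-noon study day, the longest maximal IA run
#' intersecting the nocturnal span (22:01-07:00) gives sleep onset (run
#' start), wake time (run end) and rest duration. The sample SD of
#' durations across days is the sleep-duration-variability covariate used
#' in the determinant analysis.
#'
#' @param decoding an [decode_states()] result.
#' @param night_span clock-hour pair `(start, end)` of the nocturnal
#'   window, wrapping midnight.
#' @return list with `windows` (data frame: day, onset, wake as `POSIXct`,
#'   duration_h), `sleep_duration_sd` (h; `NA` with fewer than 2 usable
#'   days) and `days_without_rest`.
#' @export
estimate_sleep_windows <- function(decoding, night_span = c(22 + 1 / 60, 7)) {
  times <- decoding$times
  bin_h <- as.numeric(difftime(times[2], times[1], units = "hours"))
  day <- study_day(times, times[1])
  n_days <- length(unique(day))
  if (n_days < 3) stop("need at least 3 study days")
  ia <- decoding$path == 1L
  in_night <- function(h) h >= night_span[1] | h <= night_span[2]
  rows <- list(); skipped <- 0L
  for (d in sort(unique(day))) {
    idx <- which(day == d)
    r <- rle(ia[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    best <- NULL
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run <- idx[starts[k]:ends[k]]
      h <- clock_hours(times[run])
      if (!any(in_night(h))) next
      if (is.null(best) || length(run) > best$len)
        best <- list(run = run, len = length(run))
    }
    if (is.null(best)) { skipped <- skipped + 1L; next }
    onset <- times[best$run[1]]
    wake <- times[best$run[best$len]] + bin_h * 3600
    rows[[length(rows) + 1L]] <-
      data.frame(day = d, onset = onset, wake = wake,
                 duration_h = best$len * bin_h)
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(day = integer(0), onset = as.POSIXct(character(0), tz = "UTC"),
               wake = as.POSIXct(character(0), tz = "UTC"),
               duration_h = numeric(0))
  sdd <- if (nrow(windows) >= 2) stats::sd(windows$duration_h) else NA_real_
  list(windows = windows, sleep_duration_sd = sdd,
       days_without_rest = skipped)
}
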