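# Determinants of I<O: Spearman screening correlations, Welch and Fisher
# group contrasts, and exhaustive AICc model selection over candidate
# predictor subsets.

#' Spearman correlations of candidate predictors with a response
#'
#' Pairwise-complete Spearman correlations (average ranks for ties) with
#' two-sided p-values. Constant predictors are reported as undefined.
#'
#' @param table data frame, one row per subject.
#' @param response name of the response column.
#' @param predictors candidate column names (default: all numeric columns
#'   except the response).
#' @param min_pairs minimum complete pairs per predictor.
#' @return data frame with `predictor`, `rho`, `p`, `n`, `undefined`.
#' @export
pairwise_correlations <- function(table, response, predictors = NULL,
                                  min_pairs = 5) {
  if (is.null(predictors)) {
    num <- vapply(table, is.numeric, logical(1))
    predictors <- setdiff(names(table)[num], response)
  }
  y <- table[[response]]
  rows <- lapply(predictors, function(p) {
    x <- table[[p]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs)
      stop("fewer than ", min_pairs, " complete pairs for ", p)
    if (stats::sd(x[ok]) == 0)
      return(data.frame(predictor = p, rho = NA_real_, p = NA_real_,
                        n = n, undefined = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(predictor = p, rho = unname(ct$estimate),
               p = ct$p.value, n = n, undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Two conventions are supported: `"minlike"` sums the probabilities of
#' all tables no more likely than the observed one (the `fisher.test`
#' definition); `"doubling"` doubles the smaller one-sided tail
#' probability (capped at 1). Software differs on this definition, so
#' both are exposed.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param convention `"minlike"` or `"doubling"`.
#' @return list with `p`, `odds_ratio`, `convention`.
#' @export
fisher_exact_2x2 <- function(tab, convention = c("minlike", "doubling")) {
  convention <- match.arg(convention)
  tab <- as.matrix(tab)
  stopifnot(dim(tab) == c(2, 2), all(tab >= 0), all(tab == round(tab)))
  ft <- stats::fisher.test(tab)
  p <- if (convention == "minlike") ft$p.value else {
    p1 <- min(stats::fisher.test(tab, alternative = "greater")$p.value,
              stats::fisher.test(tab, alternative = "less")$p.value)
    min(1, 2 * p1)
  }
  list(p = p, odds_ratio = unname(ft$estimate), convention = convention)
}

#' Group comparison: Welch t-test or Fisher exact test
#'
#' @param x for `kind = "welch"`, numeric values of the first group; for
#'   `kind = "fisher"`, a 2x2 count matrix.
#' @param y second group values (`welch` only).
#' @param kind test kind.
#' @param convention Fisher two-sided convention, see
#'   [fisher_exact_2x2()].
#' @return list with `statistic`, `p`, `df` (Welch) or `odds_ratio`
#'   (Fisher).
#' @export
group_compare <- function(x, y = NULL, kind = c("welch", "fisher"),
                          convention = "minlike") {
  kind <- match.arg(kind)
  if (kind == "fisher") {
    f <- fisher_exact_2x2(x, convention)
    return(list(statistic = f$odds_ratio, odds_ratio = f$odds_ratio,
                p = f$p))
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: identical constants are indistinguishable
    return(list(statistic = 0, p = if (mean(x) == mean(y)) 1 else 0,
                df = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Small-sample corrected AIC of a fitted lm
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `k` the number of estimated
#' parameters including the error variance.
#'
#' @param fit an `lm` fit.
#' @return AICc value (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Exhaustive AICc model selection
#'
#' Enumerates every subset of the candidate predictors up to
#' `max_predictors`, fits each by ordinary least squares (with or without
#' an intercept) on the listwise-complete rows, and returns the
#' minimum-AICc model together with the full ranked candidate table.
#' Numerically collinear subsets (condition number above `kappa_max`) are
#' skipped.
#'
#' @param table data frame, one row per subject.
#' @param response response column name.
#' @param candidates candidate predictor column names.
#' @param include_intercept fit an intercept (the printed regression
#'   equations omit one; both modes are supported).
#' @param max_predictors largest subset size.
#' @param kappa_max collinearity guard on the design condition number.
#' @return A `model_selection` list: `selected` (predictor names),
#'   `coefficients`, `adj_r_squared`, `aicc`, `n`, `n_dropped` (listwise
#'   deletions), `ranking` (data frame over all fitted subsets).
#' @export
select_model <- function(table, response, candidates,
                         include_intercept = TRUE, max_predictors = 4,
                         kappa_max = 1e10) {
  cols <- c(response, candidates)
  stopifnot(all(cols %in% names(table)))
  cc <- stats::complete.cases(table[cols])
  n_dropped <- sum(!cc)
  dat <- table[cc, cols, drop = FALSE]
  n <- nrow(dat)
  if (n <= max_predictors + 2)
    stop("too few complete rows for the requested subset size")
  subsets <- list(character(0))
  for (k in seq_len(min(max_predictors, length(candidates))))
    subsets <- c(subsets,
                 utils::combn(candidates, k, simplify = FALSE))
  rows <- list(); fits <- list()
  for (s in subsets) {
    rhs <- if (length(s)) paste(s, collapse = " + ") else
      if (include_intercept) "1" else "0"
    if (length(s) && !include_intercept) rhs <- paste(rhs, "- 1")
    fml <- stats::as.formula(paste(response, "~", rhs))
    X <- stats::model.matrix(fml, dat)
    if (ncol(X) > 1 && kappa(X, exact = TRUE) > kappa_max) next
    if (ncol(X) == 0 && !length(s)) {
      # intercept-free null model: zero-parameter mean function
      rss <- sum(dat[[response]]^2)
      ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
      k_par <- 1
      a <- -2 * ll + 2 * k_par + 2 * k_par * (k_par + 1) / (n - k_par - 1)
      rows[[length(rows) + 1]] <-
        data.frame(subset = "(none)", k = 0, aicc = a,
                   adj_r_squared = NA_real_)
      fits[length(fits) + 1] <- list(NULL)
      next
    }
    fit <- stats::lm(fml, dat)
    rows[[length(rows) + 1]] <-
      data.frame(subset = if (length(s)) paste(s, collapse = "+")
                 else "(none)",
                 k = length(s), aicc = aicc(fit),
                 adj_r_squared =
                   suppressWarnings(summary(fit)$adj.r.squared))
    fits[[length(fits) + 1]] <- fit
  }
  ranking <- do.call(rbind, rows)
  ord <- order(ranking$aicc)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  best_fit <- fits[ord][[1]]
  selected <- if (ranking$subset[1] == "(none)") character(0) else
    strsplit(ranking$subset[1], "+", fixed = TRUE)[[1]]
  structure(list(
    selected = selected,
    coefficients = if (is.null(best_fit)) numeric(0) else coef(best_fit),
    adj_r_squared = ranking$adj_r_squared[1],
    aicc = ranking$aicc[1], n = n, n_dropped = n_dropped,
    include_intercept = include_intercept, ranking = ranking),
    class = "model_selection")
}
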