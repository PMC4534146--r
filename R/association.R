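#' Wald odds ratio for a 2x2 exposure table
#'
#' Cross-product odds ratio with the Wald (log-scale normal) 95% confidence
#' interval: `OR = ad/(bc)`, `se(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `CI = exp(log OR +/- 1.96 se)`, and a two-sided normal p value on
#' `log OR / se`.
#'
#' @param a Exposed cases.
#' @param b Exposed controls.
#' @param c Reference cases.
#' @param d Reference controls.
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to every cell
#'   (required when any cell is zero; zero cells otherwise raise an error).
#' @return Object of class `or_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `se_log_or`, `p_wald`.
#' @examples
#' odds_ratio_wald(17, 5, 14, 29)  # OR 7.04, CI (2.16, 23.00)
#' @export
odds_ratio_wald <- function(a, b, c, d, haldane = FALSE) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cells must be nonnegative")
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE for the +0.5 correction")
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  structure(
    list(
      odds_ratio = exp(log_or),
      ci_low = exp(log_or - z * se),
      ci_high = exp(log_or + z * se),
      se_log_or = se,
      p_wald = 2 * stats::pnorm(-abs(log_or / se))
    ),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f, %.2f), p = %.4g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_wald))
  invisible(x)
}

#' Univariate odds ratios for the gain categories
#'
#' Computes, for each non-reference gain category, the Wald odds ratio of
#' invasive cancer relative to the `no_gains` reference from a category
#' count table (columns `category`, `dcis_only`, `dcis_ibc` as produced by
#' [tabulate_categories()]). The `unable_to_determine` stratum is excluded.
#'
#' @param category_counts Category count table.
#' @return Data frame with one row per non-reference category: `category`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_wald`.
#' @export
univariate_category_or <- function(category_counts) {
  stopifnot(all(c("category", "dcis_only", "dcis_ibc")
                %in% names(category_counts)))
  ref <- category_counts[category_counts$category == "no_gains", ]
  if (nrow(ref) != 1) stop("category table must contain a no_gains row")
  cats <- setdiff(GAIN_CATEGORIES, c("unable_to_determine", "no_gains"))
  rows <- lapply(cats, function(cc) {
    row <- category_counts[category_counts$category == cc, ]
    if (nrow(row) != 1) stop("missing category row: ", cc)
    orr <- odds_ratio_wald(row$dcis_ibc, row$dcis_only,
                           ref$dcis_ibc, ref$dcis_only)
    data.frame(category = cc, odds_ratio = orr$odds_ratio,
               ci_low = orr$ci_low, ci_high = orr$ci_high,
               p_wald = orr$p_wald, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Model specification for the invasive-cancer logistic model
#'
#' Fixes the model terms and their reference levels: gain category
#' (reference `no_gains`), age group (reference `50-64`), race collapsed to
#' non-Hispanic white / non-Hispanic Asian-Pacific Islander / other
#' (reference `other`), hormone-receptor status (reference ER/PR positive),
#' grade (reference `1`) and HER2 gain (reference `no`).
#'
#' @param terms Character vector of covariate columns to include alongside
#'   `gain_category`.
#' @return Object of class `model_spec` mapping term -> factor levels (first
#'   level is the reference).
#' @export
model_spec <- function(terms = c("gain_category", "age_group", "race",
                                 "hr_status", "grade", "her2_gain")) {
  levels <- list(
    gain_category = c("no_gains", "only_1q", "only_8q24", "only_11q13",
                      "two_of_three", "all_three"),
    age_group = c("50-64", "<40", "40-49", ">=65"),
    race = c("other", "nh_white", "nh_api"),
    hr_status = c("er_pr_positive", "er_pr_negative"),
    grade = c("1", "2", "3"),
    her2_gain = c("no", "yes")
  )
  unknown <- setdiff(terms, names(levels))
  if (length(unknown) > 0) stop("unknown terms: ", paste(unknown, collapse = ", "))
  structure(levels[terms], class = "model_spec")
}

#' Complete-case filter for the logistic model
#'
#' Retains samples with non-missing values for every model variable and a
#' determinable gain category (`unable_to_determine` counts as missing for
#' the category term).
#'
#' @param data Data frame holding the model columns.
#' @param spec A [model_spec()] object.
#' @return The complete-case subset of `data`.
#' @export
filter_complete_cases <- function(data, spec = model_spec()) {
  keep <- rep(TRUE, nrow(data))
  for (term in names(spec)) {
    if (!term %in% names(data)) stop("data lacks model column: ", term)
    v <- as.character(data[[term]])
    keep <- keep & !is.na(v) & v != ""
    if (term == "gain_category") keep <- keep & v != "unable_to_determine"
  }
  data[keep, , drop = FALSE]
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with explicit IRLS iterations:
#' convergence when the largest absolute coefficient change drops below
#' `tol` (default 1e-8) or after `max_iter` iterations, with step-halving so
#' the log-likelihood never decreases between iterations. Divergence toward
#' separation (fitted probabilities collapsing to 0/1 with unbounded
#' coefficients) is flagged via `converged = FALSE` and a diagnostic
#' message rather than an error.
#'
#' @param x Design matrix including the intercept column (e.g. from
#'   [stats::model.matrix()]).
#' @param y Binary response (0/1 or logical).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Coefficient-change convergence tolerance.
#' @return Object of class `logit_fit`: `coefficients`, `vcov`,
#'   `log_likelihood`, `loglik_trace`, `n_used`, `converged`, `diagnostic`.
#' @export
fit_logistic <- function(x, y, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("outcome is constant; model is degenerate")
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  loglik <- function(beta) {
    eta <- drop(x %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, ncol(x))
  names(beta) <- colnames(x)
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  diagnostic <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(x, z, w)
    beta_new <- fit$coefficients
    # step-halve toward the previous iterate if the likelihood would drop
    step <- 1
    ll_new <- loglik(beta_new)
    while (ll_new < ll && step > 1e-10) {
      step <- step / 2
      beta_new <- beta + step * (fit$coefficients - beta)
      ll_new <- loglik(beta_new)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  if (max(abs(beta)) > 15 && (min(p) < 1e-8 || max(p) > 1 - 1e-8)) {
    converged <- FALSE
    diagnostic <- "possible separation: coefficients diverging with fitted probabilities at 0/1"
  }
  w <- pmax(p * (1 - p), 1e-12)
  xtwx <- crossprod(x * sqrt(w))
  vcov <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(
    list(coefficients = beta, vcov = vcov, log_likelihood = ll,
         loglik_trace = trace, n_used = nrow(x), converged = converged,
         diagnostic = diagnostic),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  cat(sprintf("logistic fit (IRLS), n = %d, logLik = %.3f, converged: %s\n",
              x$n_used, x$log_likelihood, x$converged))
  print(data.frame(coef = x$coefficients, se = se,
                   OR = exp(x$coefficients)))
  invisible(x)
}

#' Multi-degree-of-freedom Wald test on model terms
#'
#' Chi-square Wald statistic `b' V^-1 b` on the selected coefficients using
#' the fitted covariance.
#'
#' @param fit A [fit_logistic()] result.
#' @param idx Integer or character index of the coefficients to test.
#' @return Two-sided p value.
#' @export
wald_test_term <- function(fit, idx) {
  b <- fit$coefficients[idx]
  v <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(v) %*% b)
  stats::pchisq(stat, df = length(b), lower.tail = FALSE)
}

#' Fit the multivariable invasive-cancer model on a cohort table
#'
#' Builds the complete-case design from a sample table carrying
#' `gain_category` and the model covariates, fits the IRLS logistic model of
#' IBC on all terms, and returns adjusted odds ratios with Wald CIs plus
#' per-term multi-df Wald p values.
#'
#' @param data Sample table with a `group` column (`"dcis_only"` /
#'   `"dcis_ibc"`) plus the model columns.
#' @param spec A [model_spec()] object.
#' @return List with the `logit_fit`, the OR table (`term`, `level`, `or`,
#'   `ci_low`, `ci_high`) and per-term Wald p values.
#' @export
fit_ibc_model <- function(data, spec = model_spec()) {
  cc <- filter_complete_cases(data, spec)
  if (nrow(cc) == 0) stop("no complete cases")
  for (term in names(spec)) {
    lev <- spec[[term]]
    v <- as.character(cc[[term]])
    bad <- setdiff(unique(v), lev)
    if (length(bad) > 0) {
      stop("term ", term, " has levels outside the model spec: ",
           paste(bad, collapse = ", "))
    }
    present <- lev[lev %in% v]
    cc[[term]] <- factor(v, levels = present)
  }
  y <- as.integer(as.character(cc$group) == "dcis_ibc")
  form <- stats::as.formula(paste("~", paste(names(spec), collapse = " + ")))
  x <- stats::model.matrix(form, data = cc)
  fit <- fit_logistic(x, y)
  assign_idx <- attr(x, "assign")
  se <- sqrt(diag(fit$vcov))
  or_table <- data.frame(
    term = c("(Intercept)", names(spec))[assign_idx + 1],
    coefficient = colnames(x),
    or = exp(fit$coefficients),
    ci_low = exp(fit$coefficients - stats::qnorm(0.975) * se),
    ci_high = exp(fit$coefficients + stats::qnorm(0.975) * se),
    stringsAsFactors = FALSE, row.names = NULL
  )
  wald <- vapply(seq_along(spec), function(k) {
    wald_test_term(fit, which(assign_idx == k))
  }, numeric(1))
  names(wald) <- names(spec)
  list(fit = fit, or_table = or_table, term_p = wald, n_used = nrow(cc))
}
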