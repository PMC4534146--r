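test_that("Wald odds ratios reproduce the published univariate column", {
  counts <- study_category_counts()
  u <- univariate_category_or(counts)
  expect_equal(round(u$odds_ratio, 2), c(2.21, 2.85, 2.07, 5.70, 7.04))
  all3 <- u[u$category == "all_three", ]
  expect_equal(round(all3$ci_low, 2), 2.16)
  expect_equal(round(all3$ci_high, 2), 23.00)
  two3 <- u[u$category == "two_of_three", ]
  expect_equal(round(c(two3$ci_low, two3$ci_high), 2), c(2.27, 14.27))
})

test_that("odds_ratio_wald handles the balanced and zero-cell cases", {
  r <- odds_ratio_wald(1, 1, 1, 1)
  expect_equal(r$odds_ratio, 1.0)
  expect_equal(log(r$ci_low), -log(r$ci_high))
  expect_error(odds_ratio_wald(3, 0, 2, 5), "zero cell")
  rh <- odds_ratio_wald(3, 0, 2, 5, haldane = TRUE)
  expect_equal(rh$odds_ratio, (3.5 * 5.5) / (0.5 * 2.5))
})

test_that("complete-case filter drops missing covariates and unknown categories", {
  d <- data.frame(
    group = "dcis_ibc",
    gain_category = c("no_gains", "all_three", "unable_to_determine",
                      "only_1q"),
    age_group = c("50-64", NA, "50-64", "<40"),
    race = "nh_white", hr_status = "er_pr_positive", grade = "2",
    her2_gain = "no", stringsAsFactors = FALSE
  )
  cc <- filter_complete_cases(d)
  expect_equal(cc$gain_category, c("no_gains", "only_1q"))
  # no missingness: identity
  expect_equal(nrow(filter_complete_cases(d[c(1, 4), ])), 2)
})

test_that("retained fraction under independent missingness matches 0.8^3", {
  set.seed(31)
  n <- 10000
  d <- data.frame(
    group = "dcis_ibc", gain_category = "no_gains",
    age_group = ifelse(runif(n) < 0.2, NA, "50-64"),
    race = ifelse(runif(n) < 0.2, NA, "other"),
    hr_status = ifelse(runif(n) < 0.2, NA, "er_pr_positive"),
    grade = "1", her2_gain = "no", stringsAsFactors = FALSE
  )
  frac <- nrow(filter_complete_cases(d)) / n
  se <- sqrt(0.8^3 * (1 - 0.8^3) / n)
  expect_lt(abs(frac - 0.8^3), 3 * se)
})

test_that("saturated logistic fit equals the closed-form 2x2 odds ratio", {
  # exposure x outcome counts: (17, 5, 14, 29)
  make_design <- function(a, b, c, d) {
    exposed <- c(rep(1, a + b), rep(0, c + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
    list(x = cbind(`(Intercept)` = 1, exposed = exposed), y = y)
  }
  for (cells in list(c(17, 5, 14, 29), c(33, 12, 14, 29), c(4, 7, 9, 3))) {
    dd <- make_design(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(dd$x, dd$y)
    ref <- odds_ratio_wald(cells[1], cells[2], cells[3], cells[4])
    expect_true(fit$converged)
    expect_equal(exp(fit$coefficients[["exposed"]]), ref$odds_ratio,
                 tolerance = 1e-7)
    expect_equal(sqrt(fit$vcov["exposed", "exposed"]), ref$se_log_or,
                 tolerance = 1e-7)
  }
})

test_that("IRLS agrees with glm and its log-likelihood never decreases", {
  set.seed(32)
  for (i in 1:10) {
    n <- 300
    x <- cbind(1, matrix(rnorm(n * 3), n))
    colnames(x) <- c("(Intercept)", "x1", "x2", "x3")
    eta <- x %*% c(-0.5, 1, -0.7, 0.3)
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_logistic(x, y)
    ref <- glm.fit(x, y, family = binomial())
    expect_equal(unname(fit$coefficients), unname(ref$coefficients),
                 tolerance = 1e-6)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    # permuting sample order leaves the estimates unchanged
    perm <- sample(n)
    fit_p <- fit_logistic(x[perm, ], y[perm])
    expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-8)
  }
})

test_that("degenerate designs are reported, not silently fitted", {
  x <- cbind(1, c(0, 0, 1, 1), c(0, 0, 2, 2))
  colnames(x) <- c("(Intercept)", "a", "b")
  expect_error(fit_logistic(x, c(0, 1, 0, 1)), "rank deficient")
  expect_error(fit_logistic(cbind(1, rnorm(4)), rep(1, 4)), "constant")
  # complete separation is flagged
  xs <- cbind(`(Intercept)` = 1, z = c(-2, -1, -1.5, 1, 1.5, 2))
  fit <- fit_logistic(xs, c(0, 0, 0, 1, 1, 1))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
})

test_that("Wald term test matches the 1-df normal test and the definition", {
  dd <- list(x = cbind(`(Intercept)` = 1,
                       exposed = c(rep(1, 22), rep(0, 43))),
             y = c(rep(1, 17), rep(0, 5), rep(1, 14), rep(0, 29)))
  fit <- fit_logistic(dd$x, dd$y)
  b <- fit$coefficients[["exposed"]]
  se <- sqrt(fit$vcov["exposed", "exposed"])
  expect_equal(wald_test_term(fit, "exposed"),
               2 * pnorm(-abs(b / se)), tolerance = 1e-12)
  # zero coefficient with identity covariance: statistic 0, p = 1
  fake <- structure(list(coefficients = c(a = 0, b = 0),
                         vcov = diag(2)), class = "logit_fit")
  dimnames(fake$vcov) <- list(c("a", "b"), c("a", "b"))
  expect_equal(wald_test_term(fake, c("a", "b")), 1.0)
})

test_that("multivariable model on a synthetic cohort returns adjusted ORs", {
  set.seed(33)
  co <- generate_cohort(cohort_config(n_dcis_only = 400, n_dcis_ibc = 400,
                                      link_mode = "logistic_link", seed = 33))
  calls <- call_loci(co$cells, grid = full_grid(co))
  pr <- build_profiles(calls)
  d <- co$samples
  d$gain_category <- as.character(
    pr$gain_category[match(d$sample_id, pr$sample_id)])
  d$her2_gain <- ifelse(pr$status_HER2[match(d$sample_id, pr$sample_id)]
                        == "gain", "yes", "no")
  res <- fit_ibc_model(d)
  expect_true(res$fit$converged)
  expect_equal(res$n_used, nrow(filter_complete_cases(d)))
  expect_true(all(c("gain_category", "her2_gain") %in% names(res$term_p)))
  expect_true(all(res$or_table$ci_low <= res$or_table$or &
                    res$or_table$or <= res$or_table$ci_high))
})
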