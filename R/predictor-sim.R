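#' Frequency and differential classes for the predictor simulation
#'
#' Base population alteration frequencies (LF 5%, MF 15%, HF 30%) and
#' case/control differential folds (ND 1.0, LD 1.25, MD 1.5, HD 3.0).
#' @name sim-classes
#' @export
FREQ_CLASSES <- c(LF = 0.05, MF = 0.15, HF = 0.30)

#' @rdname sim-classes
#' @export
DIFF_CLASSES <- c(ND = 1.0, LD = 1.25, MD = 1.5, HD = 3.0)

#' Design of the genomic-predictor simulation experiment
#'
#' Fixes the feature roster and experiment sizes: 22 binary alteration
#' features (10 low, 6 mid, 6 high frequency), of which nine are
#' differential - exactly one per frequency-by-{LD, MD, HD} cell - and the
#' remaining 13 are nondifferential; 151 cases vs 129 controls; an
#' L1-logistic predictor tuned by stratified tenfold cross-validation per
#' iteration.
#'
#' @param n_cases,n_controls Group sizes (defaults 151 and 129).
#' @param n_iterations Number of simulate-and-fit iterations (default
#'   2000).
#' @param cv_folds Cross-validation folds (default 10).
#' @param n_lambda Number of lambda-grid points (default 50, log-spaced).
#' @param lambda_min_ratio Smallest grid lambda as a fraction of the
#'   data-derived lambda_max (default 1/1000).
#' @param selection Lambda-selection rule: maximize mean held-out AUC
#'   (`"auc"`, default) or minimize mean held-out binomial deviance
#'   (`"deviance"`).
#' @param seed Master seed; each iteration gets its own substream.
#' @return Object of class `sim_design` whose `features` element lists each
#'   feature's frequency class, differential class and the implied control
#'   and case alteration probabilities (case = min(1, fold x base)).
#' @export
sim_design <- function(n_cases = 151L, n_controls = 129L,
                       n_iterations = 2000L, cv_folds = 10L,
                       n_lambda = 50L, lambda_min_ratio = 1 / 1000,
                       selection = c("auc", "deviance"), seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(n_cases >= 0, n_controls >= 0, n_iterations >= 1,
            cv_folds >= 2, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  freq <- rep(c("LF", "MF", "HF"), c(10L, 6L, 6L))
  diff <- unlist(lapply(c(10L, 6L, 6L), function(k) {
    c("LD", "MD", "HD", rep("ND", k - 3L))
  }))
  features <- data.frame(
    feature = sprintf("f%02d_%s_%s", seq_along(freq), freq, diff),
    freq_class = freq, diff_class = diff,
    control_freq = unname(FREQ_CLASSES[freq]),
    case_freq = pmin(1, unname(DIFF_CLASSES[diff] * FREQ_CLASSES[freq])),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         features = features, n_iterations = as.integer(n_iterations),
         cv_folds = as.integer(cv_folds), n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio, selection = selection,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Simulate one case/control binary alteration dataset
#'
#' Features are independent Bernoulli draws: controls at the feature's base
#' frequency, cases at min(1, fold x base).
#'
#' @param design A [sim_design()].
#' @param rng_seed Optional integer seed.
#' @return List with `x` (binary matrix, samples x features) and `y`
#'   (1 = case, 0 = control).
#' @export
generate_sim_dataset <- function(design, rng_seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n1 <- design$n_cases
  n0 <- design$n_controls
  ft <- design$features
  y <- c(rep(1L, n1), rep(0L, n0))
  x <- matrix(0L, n1 + n0, nrow(ft),
              dimnames = list(NULL, ft$feature))
  for (j in seq_len(nrow(ft))) {
    x[, j] <- c(stats::rbinom(n1, 1L, ft$case_freq[j]),
                stats::rbinom(n0, 1L, ft$control_freq[j]))
  }
  list(x = x, y = y)
}

#' Rank-based AUC of scores against binary labels
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic with midranks for ties; constant scores give 0.5.
#'
#' @param scores Numeric predictions (any monotone scale).
#' @param labels Binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' L1-regularized logistic fit with cross-validated lambda selection
#'
#' Fits the L1-penalized logistic path (cyclic coordinate descent with
#' soft-thresholding, intercept unpenalized, no standardization - the
#' features are already on a common binary scale) over a log-spaced lambda
#' grid anchored at the data-derived lambda_max (the smallest lambda that
#' zeroes every coefficient), selects lambda by stratified k-fold
#' cross-validation, and refits on the full data at the selected lambda.
#' The held-out AUC is computed on the pooled out-of-fold predictions at
#' the selected lambda. Fold assignment is stratified by label and
#' deterministic given the seed.
#'
#' @param x Binary feature matrix (samples x features).
#' @param y Binary labels (1 = case).
#' @param lambda_grid Decreasing positive lambda values; derived from the
#'   data when `NULL`.
#' @param cv_folds Number of folds.
#' @param rng_seed Optional integer seed for fold assignment.
#' @param n_lambda,lambda_min_ratio Grid shape when `lambda_grid` is
#'   derived.
#' @param selection `"auc"` (maximize mean per-fold held-out AUC; ties go
#'   to the larger, sparser lambda) or `"deviance"` (minimize mean held-out
#'   binomial deviance).
#' @return List: `selected_lambda`, `heldout_auc`, `active` (logical per
#'   feature), `n_active`, `coefficients`, `lambda_grid`, `cv_criterion`.
#' @export
fit_l1_cv <- function(x, y, lambda_grid = NULL, cv_folds = 10L,
                      rng_seed = NULL, n_lambda = 50L,
                      lambda_min_ratio = 1 / 1000,
                      selection = c("auc", "deviance")) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least two samples in each class")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(x, y - mean(y)))) / n
    lambda_grid <- exp(seq(log(lambda_max),
                           log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  stopifnot(all(diff(lambda_grid) < 0), all(lambda_grid > 0))
  nl <- length(lambda_grid)

  folds <- integer(n)
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(cv_folds),
                                                   length(idx))
  }

  pred <- matrix(NA_real_, n, nl)
  for (k in seq_len(cv_folds)) {
    te <- folds == k
    fit_k <- glmnet::glmnet(x[!te, , drop = FALSE], y[!te],
                            family = "binomial", lambda = lambda_grid,
                            standardize = FALSE)
    pred[te, ] <- stats::predict(fit_k, x[te, , drop = FALSE],
                                 s = lambda_grid, type = "link")
  }

  if (selection == "auc") {
    crit <- vapply(seq_len(nl), function(l) {
      mean(vapply(seq_len(cv_folds), function(k) {
        auc_score(pred[folds == k, l], y[folds == k])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    sel <- which.max(crit)  # ties resolve to the largest lambda
  } else {
    crit <- vapply(seq_len(nl), function(l) {
      p <- stats::plogis(pred[, l])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -2 * mean(y * log(p) + (1 - y) * log(1 - p))
    }, numeric(1))
    sel <- which.min(crit)
  }

  full <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda_grid,
                         standardize = FALSE)
  beta <- as.numeric(stats::coef(full)[-1, sel])
  names(beta) <- colnames(x)
  list(
    selected_lambda = lambda_grid[sel],
    heldout_auc = auc_score(pred[, sel], y),
    active = beta != 0,
    n_active = sum(beta != 0),
    coefficients = beta,
    lambda_grid = lambda_grid,
    cv_criterion = crit
  )
}

#' Run the genomic-predictor simulation experiment
#'
#' Executes `n_iterations` independent simulate-and-fit cycles (each with
#' its own substream of the master seed), recording per iteration the
#' held-out AUC, the number of active features and which features were
#' active, then aggregates the proportion of iterations in which each
#' frequency-by-differential class had at least one active feature.
#'
#' @param design A [sim_design()].
#' @param progress Print a dot every 100 iterations.
#' @return Object of class `sim_summary`: `selection_proportion` (data
#'   frame per class), `auc_distribution` (summary statistics),
#'   `iterations` (per-iteration records), `design`.
#' @export
run_simulation <- function(design, progress = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, design$n_iterations)
  ft <- design$features
  active <- matrix(FALSE, design$n_iterations, nrow(ft),
                   dimnames = list(NULL, ft$feature))
  auc <- numeric(design$n_iterations)
  n_active <- integer(design$n_iterations)
  sel_lambda <- numeric(design$n_iterations)
  for (i in seq_len(design$n_iterations)) {
    set.seed(iter_seeds[i])
    dat <- generate_sim_dataset(design)
    fit <- tryCatch(
      fit_l1_cv(dat$x, dat$y, cv_folds = design$cv_folds,
                n_lambda = design$n_lambda,
                lambda_min_ratio = design$lambda_min_ratio,
                selection = design$selection),
      error = function(e) stop("iteration ", i, ": ", conditionMessage(e))
    )
    active[i, ] <- fit$active
    auc[i] <- fit$heldout_auc
    n_active[i] <- fit$n_active
    sel_lambda[i] <- fit$selected_lambda
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")

  cls <- paste(ft$freq_class, ft$diff_class, sep = "x")
  class_levels <- as.vector(outer(names(FREQ_CLASSES), names(DIFF_CLASSES),
                                  paste, sep = "x"))
  class_levels <- class_levels[class_levels %in% cls]
  prop <- vapply(class_levels, function(cl) {
    mean(apply(active[, cls == cl, drop = FALSE], 1, any))
  }, numeric(1))
  sp <- data.frame(
    class = class_levels,
    freq_class = sub("x.*", "", class_levels),
    diff_class = sub(".*x", "", class_levels),
    n_features = as.integer(table(factor(cls, class_levels))),
    selection_proportion = unname(prop),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      selection_proportion = sp,
      auc_distribution = c(mean = mean(auc), sd = stats::sd(auc),
                           stats::quantile(auc, c(0.025, 0.25, 0.5, 0.75,
                                                  0.975))),
      iterations = data.frame(iteration = seq_len(design$n_iterations),
                              heldout_auc = auc, n_active = n_active,
                              selected_lambda = sel_lambda),
      active = active,
      design = design
    ),
    class = "sim_summary"
  )
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("predictor simulation: %d iterations, %d x %d samples, %d features\n",
              x$design$n_iterations, x$design$n_cases, x$design$n_controls,
              nrow(x$design$features)))
  cat(sprintf("held-out AUC: mean %.3f (sd %.3f)\n",
              x$auc_distribution[["mean"]], x$auc_distribution[["sd"]]))
  print(x$selection_proportion, row.names = FALSE)
  invisible(x)
}

#' Write a simulation summary to JSON
#'
#' Serializes per-class selection proportions and AUC distribution
#' statistics.
#'
#' @param summary A `sim_summary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_summary <- function(summary, path) {
  stopifnot(inherits(summary, "sim_summary"))
  out <- list(
    n_iterations = summary$design$n_iterations,
    n_cases = summary$design$n_cases,
    n_controls = summary$design$n_controls,
    selection_proportion = summary$selection_proportion,
    auc_distribution = as.list(summary$auc_distribution)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
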