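#' True copy-number state of one sample-locus
#'
#' The latent state from which per-cell signal counts are generated:
#' disomy (2 mean test copies), low gain (one to two additional copies),
#' high gain (more than two additional copies), deletion, a heterogeneous
#' gain carried by a subclone, or an assay failure that yields no scored
#' cells.
#'
#' @param label One of `"disomy"`, `"low_gain"`, `"high_gain"`,
#'   `"deletion"`, `"heterogeneous_gain"`, `"assay_failure"`.
#' @param mean_test_copies Mean true test-probe copies per cell; defaults by
#'   label (disomy 2, low_gain 3.5, high_gain 5.5, deletion 1,
#'   heterogeneous_gain 4).
#' @param subclone_fraction Fraction of cells carrying the gain; only
#'   meaningful (and required in (0,1)) for `heterogeneous_gain`.
#' @return Object of class `locus_state`.
#' @export
locus_state <- function(label,
                        mean_test_copies = NULL,
                        subclone_fraction = NULL) {
  labels <- c("disomy", "low_gain", "high_gain", "deletion",
              "heterogeneous_gain", "assay_failure")
  if (!label %in% labels) {
    stop("invalid state label '", label, "'; must be one of: ",
         paste(labels, collapse = ", "))
  }
  defaults <- c(disomy = 2, low_gain = 3.5, high_gain = 5.5, deletion = 1,
                heterogeneous_gain = 4, assay_failure = NA_real_)
  if (is.null(mean_test_copies)) mean_test_copies <- unname(defaults[label])
  if (label != "assay_failure" && !(is.finite(mean_test_copies) &&
                                    mean_test_copies > 0)) {
    stop("mean_test_copies must be positive")
  }
  if (label == "heterogeneous_gain") {
    if (is.null(subclone_fraction)) subclone_fraction <- 0.5
    stopifnot(subclone_fraction > 0, subclone_fraction < 1)
  } else if (!is.null(subclone_fraction)) {
    stop("subclone_fraction only applies to heterogeneous_gain")
  }
  structure(list(label = label, mean_test_copies = mean_test_copies,
                 subclone_fraction = subclone_fraction),
            class = "locus_state")
}

#' Signal-noise model for per-cell counts
#'
#' Per-cell counts are drawn Poisson around the true mean copy number
#' (`count_dispersion = "poisson"`) or set to the rounded true copies
#' (`"deterministic"`). Each observed signal may be missed independently
#' with probability `dropout_prob` (binomial thinning, applied to test and
#' control channels alike). Control probes are independent with mean
#' `control_mean_copies` (default 2, reflecting control loci that are
#' rarely altered in breast cancer).
#'
#' @param count_dispersion `"poisson"` or `"deterministic"`.
#' @param dropout_prob Per-signal dropout probability in \[0, 1\].
#' @param control_mean_copies Mean copies for each control probe.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(count_dispersion = c("poisson", "deterministic"),
                        dropout_prob = 0,
                        control_mean_copies = 2) {
  count_dispersion <- match.arg(count_dispersion)
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, control_mean_copies > 0)
  structure(list(count_dispersion = count_dispersion,
                 dropout_prob = dropout_prob,
                 control_mean_copies = control_mean_copies),
            class = "noise_model")
}

draw_counts <- function(means, noise) {
  if (noise$count_dispersion == "poisson") {
    counts <- stats::rpois(length(means), means)
  } else {
    counts <- as.integer(round(means))
  }
  if (noise$dropout_prob > 0) {
    counts <- stats::rbinom(length(counts), counts, 1 - noise$dropout_prob)
  }
  as.integer(counts)
}

#' Generate per-cell FISH signal counts for one sample-locus
#'
#' Draws `n_cells` cells from a true locus state under a noise model. For a
#' heterogeneous gain, a `subclone_fraction` share of cells (rounded) is
#' drawn at the gained mean and the remainder at disomy. An assay failure
#' yields zero rows.
#'
#' @param state A [locus_state()].
#' @param n_cells Number of cells to score.
#' @param noise A [noise_model()].
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Data frame with columns `test_count`, `control_red_count`,
#'   `control_green_count`, one row per cell.
#' @export
generate_cell_signals <- function(state, n_cells, noise = noise_model(),
                                  rng_seed = NULL) {
  stopifnot(inherits(state, "locus_state"), n_cells >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (state$label == "assay_failure" || n_cells == 0) {
    return(data.frame(test_count = integer(0),
                      control_red_count = integer(0),
                      control_green_count = integer(0)))
  }
  means <- rep(state$mean_test_copies, n_cells)
  if (state$label == "heterogeneous_gain") {
    n_sub <- round(state$subclone_fraction * n_cells)
    means <- c(rep(state$mean_test_copies, n_sub), rep(2, n_cells - n_sub))
  }
  data.frame(
    test_count = draw_counts(means, noise),
    control_red_count = draw_counts(rep(noise$control_mean_copies, n_cells),
                                    noise),
    control_green_count = draw_counts(rep(noise$control_mean_copies, n_cells),
                                      noise)
  )
}

#' Default per-group, per-locus state probabilities
#'
#' Probabilities over latent locus states for DCIS-only and DCIS-with-IBC
#' samples, derived from the published 280-sample cohort's per-locus
#' no-signal / no / yes fractions; the gained mass is split between low and
#' high gains using the published low/high gain proportions (1q 80/20,
#' 8q24 78/22, 11q13 53/47; HER2, for which no split is published, uses
#' 80/20).
#'
#' @return Nested list `[[group]][[locus]]` of named probability vectors.
#' @export
default_state_probs <- function() {
  split_gain <- c("1q" = 0.80, "8q24" = 0.78, "11q13" = 0.53, "HER2" = 0.80)
  counts <- list(
    dcis_only = list(
      "1q" = c(35, 49, 38), "8q24" = c(27, 63, 32),
      "11q13" = c(32, 71, 19), "HER2" = c(0, 84, 38)
    ),
    dcis_ibc = list(
      "1q" = c(45, 47, 66), "8q24" = c(36, 58, 64),
      "11q13" = c(42, 72, 44), "HER2" = c(0, 104, 54)
    )
  )
  lapply(counts, function(group) {
    out <- list()
    for (loc in names(group)) {
      k <- group[[loc]] / sum(group[[loc]])
      out[[loc]] <- c(assay_failure = k[1], disomy = k[2],
                      low_gain = k[3] * split_gain[[loc]],
                      high_gain = k[3] * (1 - split_gain[[loc]]))
    }
    out
  })
}

#' Default per-group covariate marginals
#'
#' Category frequencies (including a missing-value mass) for age group,
#' race, hormone-receptor status and grade, per diagnosis group, matching
#' the published patient-characteristics distribution. Race is collapsed to
#' non-Hispanic white / non-Hispanic Asian-Pacific Islander / other.
#'
#' @return Nested list `[[group]][[covariate]]` of named probability
#'   vectors; the name `"missing"` denotes `NA`.
#' @export
default_covariate_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    dcis_only = list(
      age_group = norm(c("<40" = 4, "40-49" = 43, "50-64" = 36, ">=65" = 37)),
      race = norm(c(nh_white = 81, nh_api = 30, other = 7, missing = 2)),
      hr_status = norm(c(er_pr_positive = 65, er_pr_negative = 55)),
      grade = norm(c("1" = 27, "2" = 57, "3" = 35, missing = 1))
    ),
    dcis_ibc = list(
      age_group = norm(c("<40" = 20, "40-49" = 47, "50-64" = 54, ">=65" = 30)),
      race = norm(c(nh_white = 118, nh_api = 23, other = 7, missing = 3)),
      hr_status = norm(c(er_pr_positive = 72, er_pr_negative = 67,
                         missing = 12)),
      grade = norm(c("1" = 29, "2" = 73, "3" = 48, missing = 1))
    )
  )
}

#' Default gain-category log-odds offsets
#'
#' Log-odds of invasive cancer per mutually exclusive gain category relative
#' to `no_gains`, set to the logs of the published univariate odds ratios
#' (2.21, 2.85, 2.07, 5.70, 7.04).
#'
#' @return Named numeric vector over gain categories.
#' @export
default_link_log_odds <- function() {
  c(unable_to_determine = 0, no_gains = 0,
    only_1q = log(2.21), only_8q24 = log(2.85), only_11q13 = log(2.07),
    two_of_three = log(5.70), all_three = log(7.04))
}

#' Configuration for synthetic cohort generation
#'
#' @param n_dcis_only,n_dcis_ibc Target sample counts per diagnosis group
#'   (defaults 122 and 158, the published sample split). In
#'   `logistic_link` mode the two counts set the total cohort size and the
#'   baseline (no-gains) log-odds `log(n_dcis_ibc / n_dcis_only)`, and the
#'   realized group sizes are random.
#' @param state_probs Nested list `[[group]][[locus]]` of probability
#'   vectors over state labels; see [default_state_probs()].
#' @param cells_per_sample Integer range (length 2) from which the number
#'   of scored cells per sample-locus is drawn uniformly. Default 40-100,
#'   the assay's minimum and target cell counts.
#' @param covariate_marginals See [default_covariate_marginals()].
#' @param link_mode `"state_first"` (group fixed, states drawn from the
#'   group's distribution) or `"logistic_link"` (states drawn from the
#'   DCIS-only distribution for every sample, group label then drawn from a
#'   logistic model on the sample's mutually exclusive gain category).
#' @param link_log_odds Named log-odds offsets per gain category used in
#'   `logistic_link` mode; see [default_link_log_odds()].
#' @param state_params Named list mapping state labels to
#'   [locus_state()] objects (means, subclone fraction).
#' @param shared_failure_prob Probability that a sample's tissue core is
#'   unevaluable as a whole, failing every locus whose marginal failure
#'   probability is at least this value (assay failures on one
#'   tissue-microarray core are strongly correlated across loci). Each
#'   locus keeps its configured marginal failure probability; the shared
#'   component only couples the failures. Default 0.17, which reproduces
#'   the published ~40% of samples unevaluable at one or more of the three
#'   risk loci. Set to 0 for fully independent failures.
#' @param noise A [noise_model()].
#' @param params A [call_params()] object (used to call loci in
#'   `logistic_link` mode).
#' @param seed Master integer seed; per-stage substreams are derived from
#'   it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_dcis_only = 122L, n_dcis_ibc = 158L,
                          state_probs = default_state_probs(),
                          cells_per_sample = c(40L, 100L),
                          covariate_marginals = default_covariate_marginals(),
                          link_mode = c("state_first", "logistic_link"),
                          link_log_odds = default_link_log_odds(),
                          state_params = NULL,
                          shared_failure_prob = 0.17,
                          noise = noise_model(),
                          params = call_params(),
                          seed = 1L) {
  link_mode <- match.arg(link_mode)
  stopifnot(n_dcis_only >= 0, n_dcis_ibc >= 0,
            length(cells_per_sample) == 2,
            cells_per_sample[1] <= cells_per_sample[2],
            shared_failure_prob >= 0, shared_failure_prob < 1)
  if (is.null(state_params)) {
    state_params <- list(
      disomy = locus_state("disomy"),
      low_gain = locus_state("low_gain"),
      high_gain = locus_state("high_gain"),
      deletion = locus_state("deletion"),
      heterogeneous_gain = locus_state("heterogeneous_gain"),
      assay_failure = locus_state("assay_failure")
    )
  }
  for (group in names(state_probs)) {
    for (loc in names(state_probs[[group]])) {
      p <- state_probs[[group]][[loc]]
      if (abs(sum(p) - 1) > 1e-9) {
        stop("state probabilities for ", group, "/", loc,
             " sum to ", sum(p), ", not 1")
      }
      if (any(p < 0)) stop("negative state probability for ", group, "/", loc)
    }
  }
  structure(
    list(n_dcis_only = as.integer(n_dcis_only),
         n_dcis_ibc = as.integer(n_dcis_ibc),
         state_probs = state_probs,
         cells_per_sample = as.integer(cells_per_sample),
         covariate_marginals = covariate_marginals,
         link_mode = link_mode, link_log_odds = link_log_odds,
         state_params = state_params,
         shared_failure_prob = shared_failure_prob,
         noise = noise, params = params,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Expand a (sample_id, locus, state) table into a per-cell signal table.
make_cells <- function(pairs, config) {
  labels <- pairs$state
  af <- labels == "assay_failure"
  rng <- config$cells_per_sample
  n_cells <- ifelse(af, 0L,
                    sample(seq(rng[1], rng[2]), nrow(pairs), replace = TRUE))
  idx <- rep(seq_len(nrow(pairs)), n_cells)
  if (length(idx) == 0) {
    return(data.frame(sample_id = character(0), locus = character(0),
                      cell_index = integer(0), test_count = integer(0),
                      control_red_count = integer(0),
                      control_green_count = integer(0)))
  }
  mean_of <- vapply(config$state_params, function(s) {
    if (is.na(s$mean_test_copies)) 0 else s$mean_test_copies
  }, numeric(1))
  means <- mean_of[labels][idx]
  cell_pos <- sequence(n_cells)
  het <- labels == "heterogeneous_gain"
  if (any(het)) {
    frac <- config$state_params$heterogeneous_gain$subclone_fraction
    n_sub <- round(frac * n_cells)
    in_bulk <- het[idx] & cell_pos > n_sub[idx]
    means[in_bulk] <- 2
  }
  noise <- config$noise
  data.frame(
    sample_id = pairs$sample_id[idx],
    locus = pairs$locus[idx],
    cell_index = as.integer(cell_pos),
    test_count = draw_counts(means, noise),
    control_red_count = draw_counts(rep(noise$control_mean_copies,
                                        length(means)), noise),
    control_green_count = draw_counts(rep(noise$control_mean_copies,
                                          length(means)), noise),
    stringsAsFactors = FALSE
  )
}

# Draw latent state labels for n samples at one locus, coupling assay
# failures through a per-sample shared (core-level) failure indicator while
# preserving the locus's marginal failure probability.
draw_states <- function(probs, core_fail, q) {
  n <- length(core_fail)
  p_fail <- if ("assay_failure" %in% names(probs)) probs[["assay_failure"]] else 0
  if (p_fail >= q && q > 0) {
    resid <- (p_fail - q) / (1 - q)
    fail <- core_fail | stats::runif(n) < resid
  } else {
    fail <- stats::runif(n) < p_fail
  }
  ok_probs <- probs[setdiff(names(probs), "assay_failure")]
  out <- rep("assay_failure", n)
  n_ok <- sum(!fail)
  if (n_ok > 0) {
    if (sum(ok_probs) <= 0) stop("locus state probabilities are all failure mass")
    out[!fail] <- sample(names(ok_probs), n_ok, replace = TRUE,
                         prob = ok_probs)
  }
  out
}

sample_from_marginal <- function(n, marginal) {
  if (n == 0) return(character(0))
  lev <- names(marginal)
  out <- sample(lev, n, replace = TRUE, prob = marginal)
  out[out == "missing"] <- NA_character_
  out
}

#' Generate a synthetic DCIS cohort
#'
#' Produces a cohort with per-cell FISH signal counts for the four-locus
#' panel and clinicopathologic covariates, under one of two designs. In
#' `state_first` mode each sample's diagnosis group is fixed and its latent
#' locus states are drawn from that group's state distribution. In
#' `logistic_link` mode latent states are drawn from the DCIS-only (control)
#' distribution for every sample, loci are called, and the group label is
#' drawn from a logistic model whose log-odds is the baseline
#' `log(n_dcis_ibc / n_dcis_only)` plus the configured offset for the
#' sample's mutually exclusive gain category. Fully deterministic given the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return Object of class `dcis_cohort`: a list with `samples` (one row
#'   per sample: `sample_id`, `group`, `age_group`, `race`, `hr_status`,
#'   `grade`) and `cells` (long per-cell signal table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 4)

  n_total <- config$n_dcis_only + config$n_dcis_ibc
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_total)),
    stringsAsFactors = FALSE
  )
  loci <- names(config$state_probs[[1]])
  if (n_total == 0) {
    samples$group <- character(0)
    samples$age_group <- character(0)
    samples$race <- character(0)
    samples$hr_status <- character(0)
    samples$grade <- character(0)
    return(structure(list(samples = samples,
                          cells = make_cells(
                            data.frame(sample_id = character(0),
                                       locus = character(0),
                                       state = character(0)), config)),
                     class = "dcis_cohort"))
  }

  if (config$link_mode == "state_first") {
    group <- rep(c("dcis_only", "dcis_ibc"),
                 c(config$n_dcis_only, config$n_dcis_ibc))
    set.seed(stage_seeds[1])
    core_fail <- stats::runif(n_total) < config$shared_failure_prob
    pairs <- expand.grid(sample_id = samples$sample_id, locus = loci,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs$group <- group[match(pairs$sample_id, samples$sample_id)]
    pairs$state <- NA_character_
    for (g in unique(pairs$group)) {
      for (loc in loci) {
        i <- which(pairs$group == g & pairs$locus == loc)
        cf <- core_fail[match(pairs$sample_id[i], samples$sample_id)]
        pairs$state[i] <- draw_states(config$state_probs[[g]][[loc]], cf,
                                      config$shared_failure_prob)
      }
    }
    set.seed(stage_seeds[2])
    cells <- make_cells(pairs, config)
  } else {
    if (config$n_dcis_only == 0 || config$n_dcis_ibc == 0) {
      stop("logistic_link mode needs positive counts in both groups to set the baseline odds")
    }
    set.seed(stage_seeds[1])
    core_fail <- stats::runif(n_total) < config$shared_failure_prob
    pairs <- expand.grid(sample_id = samples$sample_id, locus = loci,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs$state <- NA_character_
    for (loc in loci) {
      i <- which(pairs$locus == loc)
      cf <- core_fail[match(pairs$sample_id[i], samples$sample_id)]
      pairs$state[i] <- draw_states(config$state_probs[["dcis_only"]][[loc]],
                                    cf, config$shared_failure_prob)
    }
    set.seed(stage_seeds[2])
    cells <- make_cells(pairs, config)
    calls <- call_loci(cells, config$params,
                       grid = pairs[, c("sample_id", "locus")])
    profiles <- build_profiles(calls, loci = loci)
    cat_of <- as.character(profiles$gain_category)[
      match(samples$sample_id, profiles$sample_id)]
    eta <- log(config$n_dcis_ibc / config$n_dcis_only) +
      unname(config$link_log_odds[cat_of])
    set.seed(stage_seeds[3])
    group <- ifelse(stats::runif(n_total) < stats::plogis(eta),
                    "dcis_ibc", "dcis_only")
  }

  samples$group <- group
  set.seed(stage_seeds[4])
  for (cov in c("age_group", "race", "hr_status", "grade")) {
    samples[[cov]] <- NA_character_
    for (g in c("dcis_only", "dcis_ibc")) {
      i <- samples$group == g
      samples[[cov]][i] <-
        sample_from_marginal(sum(i), config$covariate_marginals[[g]][[cov]])
    }
  }
  rownames(samples) <- NULL
  structure(list(samples = samples, cells = cells), class = "dcis_cohort")
}

#' @export
print.dcis_cohort <- function(x, ...) {
  cat(sprintf("synthetic DCIS cohort: %d samples (%d DCIS-only, %d DCIS+IBC), %d scored cells\n",
              nrow(x$samples), sum(x$samples$group == "dcis_only"),
              sum(x$samples$group == "dcis_ibc"), nrow(x$cells)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `cohort.csv` (one row per sample; missing covariates as empty
#' strings) and `cells.csv` (long per-cell signal table; sample-locus pairs
#' absent from the table are assay failures) into a directory.
#'
#' @param cohort A `dcis_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dcis_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$samples, file.path(dir, "cohort.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(c))` reproduces
#' `c`. Malformed rows (negative or non-integer counts) raise an error that
#' names the offending file line.
#'
#' @param dir Directory holding `cohort.csv` and `cells.csv`.
#' @return A `dcis_cohort`.
#' @export
read_cohort <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "cohort.csv"),
                             colClasses = "character", na.strings = "")
  needed_s <- c("sample_id", "group", "age_group", "race", "hr_status",
                "grade")
  if (!all(needed_s %in% names(samples))) {
    stop("cohort.csv lacks columns: ",
         paste(setdiff(needed_s, names(samples)), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in cohort.csv")
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           colClasses = c(sample_id = "character",
                                          locus = "character"),
                           na.strings = "")
  needed_c <- c("sample_id", "locus", "cell_index", "test_count",
                "control_red_count", "control_green_count")
  if (!all(needed_c %in% names(cells))) {
    stop("cells.csv lacks columns: ",
         paste(setdiff(needed_c, names(cells)), collapse = ", "))
  }
  for (col in c("cell_index", "test_count", "control_red_count",
                "control_green_count")) {
    v <- cells[[col]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      stop("cells.csv line ", bad[1] + 1L, ": column '", col,
           "' must be a nonnegative integer")
    }
    cells[[col]] <- as.integer(v)
  }
  rownames(samples) <- NULL
  rownames(cells) <- NULL
  structure(list(samples = samples, cells = cells), class = "dcis_cohort")
}
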