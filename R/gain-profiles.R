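#' Mutually exclusive gain categories
#'
#' Levels of the six-level per-sample classification built from the three
#' risk loci (1q, 8q24, 11q13); HER2 never enters the category.
#' @export
GAIN_CATEGORIES <- c("unable_to_determine", "no_gains", "only_1q",
                     "only_8q24", "only_11q13", "two_of_three", "all_three")

#' Reshape per-locus calls to one row per sample
#'
#' @param calls Data frame of per-locus calls as produced by [call_loci()].
#' @param loci Loci expected for every sample (default the full panel).
#' @return Data frame with one row per sample and a `status_<locus>` column
#'   per locus.
#' @export
profile_calls <- function(calls, loci = FISH_LOCI) {
  missing_loci <- setdiff(loci, unique(calls$locus))
  if (length(missing_loci) > 0) {
    stop("calls table lacks loci: ", paste(missing_loci, collapse = ", "))
  }
  ids <- unique(calls$sample_id)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (loc in loci) {
    sub <- calls[calls$locus == loc, ]
    idx <- match(ids, sub$sample_id)
    if (anyNA(idx)) {
      stop("samples missing a call for locus ", loc, ": ",
           paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
    }
    out[[paste0("status_", loc)]] <- sub$status[idx]
  }
  out
}

#' Combination gain status for a set of loci
#'
#' A sample is `"yes"` for a combination when every member locus is gained,
#' `"no_signal"` when any member locus is unevaluable, and `"no"` otherwise.
#'
#' @param profiles Data frame from [profile_calls()].
#' @param loci Character vector naming the member loci of the combination.
#' @return Character vector (`"yes"`, `"no"`, `"no_signal"`), one per sample.
#' @export
combo_status <- function(profiles, loci) {
  stopifnot(length(loci) >= 1, all(loci %in% FISH_LOCI))
  cols <- paste0("status_", loci)
  stopifnot(all(cols %in% names(profiles)))
  mat <- as.matrix(profiles[, cols, drop = FALSE])
  any_ns <- rowSums(mat == "no_signal") > 0
  all_gain <- rowSums(mat == "gain") == length(loci)
  ifelse(any_ns, "no_signal", ifelse(all_gain, "yes", "no"))
}

#' Mutually exclusive six-level gain category
#'
#' Classifies each sample by its gains among the three risk loci. A sample
#' is `"unable_to_determine"` when any of 1q, 8q24, 11q13 is unevaluable
#' (HER2 is ignored); otherwise it is categorized by the set of gained loci,
#' with deleted and no-gain calls both counting as not gained.
#'
#' @param profiles Data frame from [profile_calls()].
#' @return Factor with levels [GAIN_CATEGORIES], one per sample.
#' @export
gain_category <- function(profiles) {
  cols <- paste0("status_", c("1q", "8q24", "11q13"))
  if (!all(cols %in% names(profiles))) {
    stop("profiles must contain calls for loci 1q, 8q24 and 11q13")
  }
  mat <- as.matrix(profiles[, cols, drop = FALSE])
  unable <- rowSums(mat == "no_signal") > 0
  g <- mat == "gain"
  ngain <- rowSums(g)
  cat <- rep("no_gains", nrow(profiles))
  cat[ngain == 1 & g[, 1]] <- "only_1q"
  cat[ngain == 1 & g[, 2]] <- "only_8q24"
  cat[ngain == 1 & g[, 3]] <- "only_11q13"
  cat[ngain == 2] <- "two_of_three"
  cat[ngain == 3] <- "all_three"
  cat[unable] <- "unable_to_determine"
  factor(cat, levels = GAIN_CATEGORIES)
}

#' Build per-sample gain profiles with category
#'
#' @inheritParams profile_calls
#' @return Data frame with per-locus statuses plus `gain_category`.
#' @export
build_profiles <- function(calls, loci = FISH_LOCI) {
  out <- profile_calls(calls, loci)
  out$gain_category <- gain_category(out)
  out
}

#' Prevalence table for loci and combinations
#'
#' Tabulates, per marker (each single locus and each requested combination),
#' the number of samples with status no_signal / no / yes overall and within
#' each diagnosis group, with percentages of the group total and the
#' percentage of signal-evaluable samples that are gained
#' (`yes / (yes + no)`).
#'
#' @param profiles Data frame from [build_profiles()].
#' @param groups Character or factor vector of group labels (`"dcis_only"`,
#'   `"dcis_ibc"`) aligned with `profiles` rows.
#' @param combos List of character vectors, each a locus combination to
#'   tabulate in addition to the single loci.
#' @return Data frame with one row per marker-status pair.
#' @export
tabulate_prevalence <- function(profiles, groups,
                                combos = list(
                                  c("1q", "8q24"), c("1q", "11q13"),
                                  c("8q24", "11q13"),
                                  c("1q", "8q24", "11q13"))) {
  stopifnot(length(groups) == nrow(profiles))
  groups <- as.character(groups)
  markers <- c(as.list(FISH_LOCI), combos)
  rows <- lapply(markers, function(loci) {
    st <- combo_status(profiles, loci)
    marker <- paste(loci, collapse = "+")
    data.frame(
      marker = marker,
      status = c("no_signal", "no", "yes"),
      all = c(sum(st == "no_signal"), sum(st == "no"), sum(st == "yes")),
      dcis_only = c(sum(st == "no_signal" & groups == "dcis_only"),
                    sum(st == "no" & groups == "dcis_only"),
                    sum(st == "yes" & groups == "dcis_only")),
      dcis_ibc = c(sum(st == "no_signal" & groups == "dcis_ibc"),
                   sum(st == "no" & groups == "dcis_ibc"),
                   sum(st == "yes" & groups == "dcis_ibc")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- add_prevalence_pcts(out, n_all = nrow(profiles),
                             n_only = sum(groups == "dcis_only"),
                             n_ibc = sum(groups == "dcis_ibc"))
  out
}

#' Percentage columns for a marker-status count table
#'
#' Adds group percentages and the evaluable-gain percentage to a long table
#' of marker-by-status counts (columns `marker`, `status`, `all`,
#' `dcis_only`, `dcis_ibc`). Works on generated cohorts and on printed
#' fixture counts alike.
#'
#' @param counts Long count table as described above.
#' @param n_all,n_only,n_ibc Group totals used as percentage denominators;
#'   by default recovered from each marker's own column sums.
#' @return `counts` with `pct_all`, `pct_only`, `pct_ibc` and, on `yes`
#'   rows, `pct_gained_evaluable` = 100 * yes / (yes + no).
#' @export
add_prevalence_pcts <- function(counts, n_all = NULL, n_only = NULL,
                                n_ibc = NULL) {
  stopifnot(all(c("marker", "status", "all", "dcis_only", "dcis_ibc")
                %in% names(counts)))
  if (is.null(n_all)) n_all <- max(tapply(counts$all, counts$marker, sum))
  if (is.null(n_only)) n_only <- max(tapply(counts$dcis_only, counts$marker, sum))
  if (is.null(n_ibc)) n_ibc <- max(tapply(counts$dcis_ibc, counts$marker, sum))
  pct <- function(x, n) if (n > 0) 100 * x / n else NA_real_
  counts$pct_all <- pct(counts$all, n_all)
  counts$pct_only <- pct(counts$dcis_only, n_only)
  counts$pct_ibc <- pct(counts$dcis_ibc, n_ibc)
  counts$pct_gained_evaluable <- NA_real_
  for (m in unique(counts$marker)) {
    i <- counts$marker == m
    yes <- counts$all[i & counts$status == "yes"]
    no <- counts$all[i & counts$status == "no"]
    if (length(yes) == 1 && length(no) == 1 && yes + no > 0) {
      counts$pct_gained_evaluable[i & counts$status == "yes"] <-
        100 * yes / (yes + no)
    }
  }
  counts
}

#' Tabulate the mutually exclusive gain categories
#'
#' @inheritParams tabulate_prevalence
#' @return Data frame with one row per category and counts overall and per
#'   group.
#' @export
tabulate_categories <- function(profiles, groups) {
  stopifnot(length(groups) == nrow(profiles))
  groups <- as.character(groups)
  cat <- profiles$gain_category
  if (is.null(cat)) cat <- gain_category(profiles)
  data.frame(
    category = GAIN_CATEGORIES,
    all = as.integer(table(factor(cat, GAIN_CATEGORIES))),
    dcis_only = as.integer(table(factor(cat[groups == "dcis_only"],
                                        GAIN_CATEGORIES))),
    dcis_ibc = as.integer(table(factor(cat[groups == "dcis_ibc"],
                                       GAIN_CATEGORIES))),
    stringsAsFactors = FALSE
  )
}
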