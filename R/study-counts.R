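#' Published cohort count fixtures
#'
#' Accessors for the printed contingency counts of the 280-sample DCIS
#' case-control FISH study that this package's pipeline re-derives:
#' per-marker gain counts (no_signal / no / yes by diagnosis group), the
#' mutually exclusive gain-category counts, and the per-marker diagnostic
#' 2x2 cells. These are shipped as plain CSV under `inst/extdata` and are
#' the inputs for the fixed-count reproduction analyses.
#'
#' @return A data frame; see each accessor.
#' @name study-counts
NULL

study_csv <- function(name) {
  path <- system.file("extdata", name, package = "dcisgain")
  if (path == "") path <- file.path("inst", "extdata", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn study-counts Marker-by-status gain counts (columns `marker`,
#'   `status`, `all`, `dcis_only`, `dcis_ibc`). The published
#'   `8q24+11q13+HER2` row carries no `yes` line and an internally
#'   inconsistent no-signal count; it is shipped verbatim and excluded from
#'   derived analyses.
#' @export
study_gain_counts <- function() study_csv("study_gain_counts.csv")

#' @describeIn study-counts Mutually exclusive gain-category counts
#'   (columns `category`, `all`, `dcis_only`, `dcis_ibc`); categories
#'   partition the 280 samples.
#' @export
study_category_counts <- function() study_csv("study_category_counts.csv")

#' @describeIn study-counts Diagnostic 2x2 cells per marker (columns
#'   `marker`, `all_cases`, `ibc`, `dcis_only`, `tp`, `fn`, `fp`, `tn`).
#' @export
study_diagnostic_counts <- function() study_csv("study_diagnostic_counts.csv")

#' Diagnostic 2x2 tables from the published counts
#'
#' @return Named list of [two_by_two()] objects, one per marker.
#' @export
study_two_by_two <- function() {
  d <- study_diagnostic_counts()
  tables <- lapply(seq_len(nrow(d)), function(i) {
    two_by_two(tp = d$tp[i], fp = d$fp[i], fn = d$fn[i], tn = d$tn[i])
  })
  names(tables) <- d$marker
  tables
}
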