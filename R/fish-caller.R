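#' @title FISH locus panel
#' @description The four loci assayed: three risk loci (1q, 8q24, 11q13) and
#'   HER2 (17q12), each hybridized together with the 3q25 (red) and 2q37
#'   (green) control probes.
#' @format Character vector of locus labels.
#' @export
FISH_LOCI <- c("1q", "8q24", "11q13", "HER2")

#' Scoring parameters for FISH copy-number calls
#'
#' Thresholds for converting per-cell probe counts into a categorical
#' per-locus call. Defaults follow the clinical scoring convention used for
#' breast-cancer FISH: a sample is gained when the test/control signal ratio
#' exceeds 1.5 or the mean number of test signals per cell exceeds 3; deleted
#' when the ratio falls below 0.75 (or more than `heterogeneity_fraction` of
#' cells individually do); unevaluable ("no signal") below `min_cells` scored
#' cells.
#'
#' @param gain_ratio_threshold Ratio above which a sample is called gained
#'   (strict inequality). Default 1.5.
#' @param gain_signals_per_cell Mean test signals per cell above which a
#'   sample is called gained (strict inequality). Default 3.
#' @param deletion_ratio_threshold Ratio below which a sample (or cell) is
#'   called deleted (strict inequality). Default 0.75.
#' @param heterogeneity_fraction Fraction of scored cells with a discordant
#'   per-cell call at or above which the sample is flagged heterogeneous;
#'   also the cell-fraction cutoff (strictly exceeded) for the cell-level
#'   deletion rule. Default 0.25.
#' @param min_cells Minimum number of scored cells for an evaluable call;
#'   fewer yields status `"no_signal"`. Default 40.
#' @param target_cells Number of cells the assay aims to score per sample
#'   (informational). Default 100.
#' @param pool_controls How the two control probes form the ratio
#'   denominator: `"mean"` pools them by averaging their totals (default);
#'   `"strict"` requires the ratio criterion to hold against each control
#'   total separately.
#' @return An object of class `call_params`.
#' @export
call_params <- function(gain_ratio_threshold = 1.5,
                        gain_signals_per_cell = 3,
                        deletion_ratio_threshold = 0.75,
                        heterogeneity_fraction = 0.25,
                        min_cells = 40L,
                        target_cells = 100L,
                        pool_controls = c("mean", "strict")) {
  pool_controls <- match.arg(pool_controls)
  stopifnot(
    deletion_ratio_threshold > 0, deletion_ratio_threshold < 1,
    gain_ratio_threshold > 1,
    heterogeneity_fraction > 0, heterogeneity_fraction < 1,
    min_cells >= 1
  )
  structure(
    list(
      gain_ratio_threshold = gain_ratio_threshold,
      gain_signals_per_cell = gain_signals_per_cell,
      deletion_ratio_threshold = deletion_ratio_threshold,
      heterogeneity_fraction = heterogeneity_fraction,
      min_cells = as.integer(min_cells),
      target_cells = as.integer(target_cells),
      pool_controls = pool_controls
    ),
    class = "call_params"
  )
}

validate_cells <- function(cells) {
  needed <- c("test_count", "control_red_count", "control_green_count")
  if (!all(needed %in% names(cells))) {
    stop("cell table must have columns: ", paste(needed, collapse = ", "))
  }
  for (col in needed) {
    v <- cells[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("column '", col, "' must contain nonnegative integer counts")
    }
  }
  invisible(cells)
}

#' Pooled test/control signal ratio for one sample-locus
#'
#' Total test-probe signals divided by the mean of the two control-probe
#' totals. Cells in which both control probes yielded zero signals carry no
#' ratio information and are excluded from all three totals.
#'
#' @param cells Data frame with columns `test_count`, `control_red_count`,
#'   `control_green_count` (one row per scored cell).
#' @return The pooled ratio, a nonnegative number.
#' @examples
#' cells <- data.frame(test_count = c(3, 3, 2),
#'                     control_red_count = c(2, 2, 1),
#'                     control_green_count = c(2, 2, 3))
#' sample_ratio(cells)  # 8 / mean(5, 7) = 1.333...
#' @export
sample_ratio <- function(cells) {
  validate_cells(cells)
  if (nrow(cells) == 0) stop("no cells scored: ratio undefined")
  usable <- cells$control_red_count + cells$control_green_count > 0
  tot_red <- sum(cells$control_red_count[usable])
  tot_green <- sum(cells$control_green_count[usable])
  if (tot_red + tot_green == 0) stop("all control counts zero: ratio undefined")
  sum(cells$test_count[usable]) / mean(c(tot_red, tot_green))
}

#' Per-cell gain/deletion/neutral status
#'
#' Classifies each scored cell by its own test-to-control ratio (test count
#' over the mean of the two control counts): gain above
#' `gain_ratio_threshold` or when the test count alone exceeds
#' `gain_signals_per_cell`; deleted below `deletion_ratio_threshold`; neutral
#' otherwise. Gain takes precedence when both rules fire. Cells with zero
#' counts for both controls have no defined ratio and can only trigger the
#' test-count gain rule.
#'
#' @inheritParams sample_ratio
#' @param params A [call_params()] object.
#' @return Character vector (`"gain"`, `"deleted"`, `"neutral"`), one per cell.
#' @export
per_cell_status <- function(cells, params = call_params()) {
  validate_cells(cells)
  denom <- (cells$control_red_count + cells$control_green_count) / 2
  ratio <- ifelse(denom > 0, cells$test_count / denom, NA_real_)
  gain <- (!is.na(ratio) & ratio > params$gain_ratio_threshold) |
    cells$test_count > params$gain_signals_per_cell
  deleted <- !gain & !is.na(ratio) & ratio < params$deletion_ratio_threshold
  status <- rep("neutral", nrow(cells))
  status[deleted] <- "deleted"
  status[gain] <- "gain"
  status
}

#' Call copy-number status for one sample-locus
#'
#' Applies the sample-level scoring rules to the scored cells of one
#' sample-locus: fewer than `min_cells` cells yields `"no_signal"`; a pooled
#' ratio above `gain_ratio_threshold` or mean test signals per cell above
#' `gain_signals_per_cell` yields `"gain"`; a pooled ratio below
#' `deletion_ratio_threshold`, or a per-cell-deleted fraction strictly above
#' `heterogeneity_fraction`, yields `"deleted"` (gain takes precedence);
#' otherwise `"no_gain"`. A sample is flagged heterogeneous when the minority
#' side of the per-cell gain/non-gain partition holds at least
#' `heterogeneity_fraction` of the scored cells.
#'
#' @inheritParams per_cell_status
#' @param sample_id,locus Identifiers carried into the result.
#' @return A one-row data frame with columns `sample_id`, `locus`, `status`,
#'   `heterogeneous`, `ratio`, `mean_signals_per_cell`, `n_cells_scored`.
#'   `ratio` and `mean_signals_per_cell` are `NA` when status is
#'   `"no_signal"`.
#' @export
call_locus <- function(cells, params = call_params(),
                       sample_id = NA_character_, locus = NA_character_) {
  validate_cells(cells)
  n <- nrow(cells)
  if (n < params$min_cells) {
    return(data.frame(
      sample_id = sample_id, locus = locus, status = "no_signal",
      heterogeneous = FALSE, ratio = NA_real_,
      mean_signals_per_cell = NA_real_, n_cells_scored = n,
      stringsAsFactors = FALSE
    ))
  }
  usable <- cells$control_red_count + cells$control_green_count > 0
  tot_test <- sum(cells$test_count[usable])
  tot_red <- sum(cells$control_red_count[usable])
  tot_green <- sum(cells$control_green_count[usable])
  ratio <- tot_test / mean(c(tot_red, tot_green))
  mean_signals <- mean(cells$test_count)

  if (params$pool_controls == "strict") {
    gain_ratio_ok <- tot_red > 0 && tot_green > 0 &&
      tot_test / tot_red > params$gain_ratio_threshold &&
      tot_test / tot_green > params$gain_ratio_threshold
    del_ratio_ok <- tot_test / max(tot_red, 1) < params$deletion_ratio_threshold &&
      tot_test / max(tot_green, 1) < params$deletion_ratio_threshold
  } else {
    gain_ratio_ok <- ratio > params$gain_ratio_threshold
    del_ratio_ok <- ratio < params$deletion_ratio_threshold
  }

  cell_status <- per_cell_status(cells, params)
  denom <- (cells$control_red_count + cells$control_green_count) / 2
  cell_ratio <- ifelse(denom > 0, cells$test_count / denom, NA_real_)
  frac_del_cells <- sum(!is.na(cell_ratio) &
                          cell_ratio < params$deletion_ratio_threshold) / n

  is_gain <- gain_ratio_ok || mean_signals > params$gain_signals_per_cell
  is_del <- !is_gain &&
    (del_ratio_ok || frac_del_cells > params$heterogeneity_fraction)
  status <- if (is_gain) "gain" else if (is_del) "deleted" else "no_gain"

  frac_gain_cells <- mean(cell_status == "gain")
  minority <- min(frac_gain_cells, 1 - frac_gain_cells)
  heterogeneous <- minority >= params$heterogeneity_fraction

  data.frame(
    sample_id = sample_id, locus = locus, status = status,
    heterogeneous = heterogeneous, ratio = ratio,
    mean_signals_per_cell = mean_signals, n_cells_scored = n,
    stringsAsFactors = FALSE
  )
}

#' Call every sample-locus in a cell table
#'
#' Vectorized application of [call_locus()] across a long table of per-cell
#' counts. Sample-locus pairs listed in `grid` but absent from `cells` (assay
#' failures, which produce no scored cells) are called `"no_signal"` with
#' zero cells.
#'
#' @param cells Data frame with columns `sample_id`, `locus`, `test_count`,
#'   `control_red_count`, `control_green_count`.
#' @param params A [call_params()] object (only `pool_controls = "mean"` is
#'   supported by the vectorized path).
#' @param grid Optional data frame with columns `sample_id`, `locus` giving
#'   the complete set of expected sample-locus pairs; defaults to the pairs
#'   present in `cells`.
#' @return Data frame of calls, one row per sample-locus, with the columns of
#'   [call_locus()].
#' @export
call_loci <- function(cells, params = call_params(), grid = NULL) {
  stopifnot(all(c("sample_id", "locus") %in% names(cells)))
  if (params$pool_controls != "mean") {
    stop("call_loci supports pool_controls = 'mean'; use call_locus for strict mode")
  }
  if (nrow(cells) > 0) validate_cells(cells)
  if (is.null(grid)) {
    grid <- unique(cells[, c("sample_id", "locus")])
  }
  key <- paste(cells$sample_id, cells$locus, sep = "\r")
  gkey <- paste(grid$sample_id, grid$locus, sep = "\r")
  key <- factor(key, levels = gkey)
  if (anyNA(key)) stop("cells table contains sample-locus pairs missing from grid")

  n <- as.integer(table(key))
  usable <- cells$control_red_count + cells$control_green_count > 0
  agg <- function(x) {
    out <- numeric(length(gkey))
    if (length(x) > 0) {
      s <- rowsum(x, key)
      out[match(rownames(s), gkey)] <- s
    }
    out
  }
  tot_test_u <- agg(cells$test_count * usable)
  tot_red_u <- agg(cells$control_red_count * usable)
  tot_green_u <- agg(cells$control_green_count * usable)
  tot_test_all <- agg(cells$test_count)

  denom <- (cells$control_red_count + cells$control_green_count) / 2
  cell_ratio <- ifelse(denom > 0, cells$test_count / denom, NA_real_)
  cell_gain <- (!is.na(cell_ratio) & cell_ratio > params$gain_ratio_threshold) |
    cells$test_count > params$gain_signals_per_cell
  cell_del_ratio <- !is.na(cell_ratio) &
    cell_ratio < params$deletion_ratio_threshold

  n_gain_cells <- agg(as.numeric(cell_gain))
  n_del_cells <- agg(as.numeric(cell_del_ratio))

  pooled_denom <- (tot_red_u + tot_green_u) / 2
  ratio <- ifelse(pooled_denom > 0, tot_test_u / pooled_denom, NA_real_)
  mean_signals <- ifelse(n > 0, tot_test_all / n, NA_real_)

  evaluable <- n >= params$min_cells
  if (any(evaluable & pooled_denom == 0)) {
    stop("all control counts zero for an evaluable sample-locus: ratio undefined")
  }
  is_gain <- evaluable & (ratio > params$gain_ratio_threshold |
                            mean_signals > params$gain_signals_per_cell)
  frac_del <- ifelse(n > 0, n_del_cells / n, 0)
  is_del <- evaluable & !is_gain &
    (ratio < params$deletion_ratio_threshold |
       frac_del > params$heterogeneity_fraction)

  status <- rep("no_signal", length(gkey))
  status[evaluable] <- "no_gain"
  status[is_del] <- "deleted"
  status[is_gain] <- "gain"

  frac_gain <- ifelse(n > 0, n_gain_cells / n, 0)
  minority <- pmin(frac_gain, 1 - frac_gain)
  heterogeneous <- evaluable & minority >= params$heterogeneity_fraction

  data.frame(
    sample_id = grid$sample_id, locus = grid$locus, status = status,
    heterogeneous = heterogeneous,
    ratio = ifelse(evaluable, ratio, NA_real_),
    mean_signals_per_cell = ifelse(evaluable, mean_signals, NA_real_),
    n_cells_scored = n, stringsAsFactors = FALSE
  )
}
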