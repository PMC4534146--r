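#' 2x2 diagnostic contingency table
#'
#' Cell layout against the invasive-cancer label: `tp` = marker-positive
#' with IBC, `fp` = marker-positive DCIS-only, `fn` = marker-negative with
#' IBC, `tn` = marker-negative DCIS-only.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("all four cells must be nonnegative integers")
  }
  structure(as.list(cells), total = sum(cells), class = "two_by_two")
}

#' Build the marker-vs-IBC 2x2 table from profiles
#'
#' Marker-positive means combination status `"yes"` for the given locus set;
#' samples with combination status `"no_signal"` are excluded, so the table
#' total varies by marker.
#'
#' @param profiles Data frame from [build_profiles()].
#' @param groups Group labels (`"dcis_only"` / `"dcis_ibc"`) aligned with
#'   `profiles`.
#' @param marker Character vector of member loci.
#' @return A [two_by_two()] object.
#' @export
build_two_by_two <- function(profiles, groups, marker) {
  stopifnot(length(groups) == nrow(profiles))
  groups <- as.character(groups)
  st <- combo_status(profiles, marker)
  keep <- st != "no_signal"
  pos <- st == "yes"
  ibc <- groups == "dcis_ibc"
  two_by_two(
    tp = sum(keep & pos & ibc),
    fp = sum(keep & pos & !ibc),
    fn = sum(keep & !pos & ibc),
    tn = sum(keep & !pos & !ibc)
  )
}

#' Diagnostic performance of a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value as
#' percentages, plus the two-tailed exact Fisher p value. A measure whose
#' denominator is zero is reported as `NA`, not 0.
#'
#' @param t A [two_by_two()] object.
#' @return Data frame with columns `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percent) and `fisher_p`.
#' @export
performance <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  data.frame(
    sensitivity = pct(t$tp, t$tp + t$fn),
    specificity = pct(t$tn, t$tn + t$fp),
    ppv = pct(t$tp, t$tp + t$fp),
    npv = pct(t$tn, t$tn + t$fn),
    fisher_p = fisher_exact_two_tailed(t)
  )
}

#' Two-tailed exact Fisher test for a 2x2 table
#'
#' Exact enumeration under the conditional hypergeometric null with fixed
#' margins. The two-tailed p value is the total probability of all tables
#' whose point probability does not exceed that of the observed table
#' (within relative tolerance 1e-7), the probability-mass convention of
#' mainstream statistical software. No asymptotic approximation and no
#' continuity correction. Any zero margin gives p = 1 by convention.
#'
#' @param t A [two_by_two()] object.
#' @return Two-tailed p value in \[0, 1\].
#' @export
fisher_exact_two_tailed <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  n_ibc <- t$tp + t$fn
  n_ctrl <- t$fp + t$tn
  n_pos <- t$tp + t$fp
  n_neg <- t$fn + t$tn
  total <- n_ibc + n_ctrl
  if (total == 0) stop("empty table")
  if (n_ibc == 0 || n_ctrl == 0 || n_pos == 0 || n_neg == 0) return(1.0)
  support <- max(0, n_pos - n_ctrl):min(n_pos, n_ibc)
  dens <- stats::dhyper(support, n_ibc, n_ctrl, n_pos)
  p_obs <- stats::dhyper(t$tp, n_ibc, n_ctrl, n_pos)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Diagnostic-performance table across markers
#'
#' Mirrors a per-marker performance layout: one column block per marker with
#' table composition, the four cells, the performance percentages and the
#' Fisher p.
#'
#' @param tables Named list of [two_by_two()] objects (names are marker
#'   labels).
#' @return Data frame, one row per marker.
#' @export
diagnostic_table <- function(tables) {
  rows <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    perf <- performance(t)
    cbind(
      data.frame(marker = nm,
                 all_cases = t$tp + t$fp + t$fn + t$tn,
                 ibc = t$tp + t$fn, dcis_only = t$fp + t$tn,
                 tp = t$tp, fn = t$fn, fp = t$fp, tn = t$tn,
                 stringsAsFactors = FALSE),
      perf
    )
  })
  do.call(rbind, rows)
}
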