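# Independent oracles used to cross-check package implementations.
# These deliberately re-derive each quantity from first principles
# (loops, choose() products, grid searches) rather than sharing code with
# the package's vectorized/aggregated paths.

# Exact two-tailed Fisher p by direct enumeration with choose() products.
oracle_fisher_p <- function(tp, fp, fn, tn) {
  r1 <- tp + fp   # marker-positive
  r2 <- fn + tn
  c1 <- tp + fn   # IBC
  c2 <- fp + tn
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(c2, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[ks == tp]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Rule-by-rule re-implementation of the FISH locus caller using plain
# per-cell loops.
oracle_call_locus <- function(cells, params = call_params()) {
  n <- nrow(cells)
  if (n < params$min_cells) {
    return(list(status = "no_signal", heterogeneous = FALSE))
  }
  tot_t <- 0; tot_r <- 0; tot_g <- 0
  n_cell_gain <- 0; n_cell_del <- 0
  for (i in seq_len(n)) {
    t <- cells$test_count[i]
    r <- cells$control_red_count[i]
    g <- cells$control_green_count[i]
    if (r + g > 0) {
      tot_t <- tot_t + t; tot_r <- tot_r + r; tot_g <- tot_g + g
      cell_ratio <- t / ((r + g) / 2)
    } else {
      cell_ratio <- NA_real_
    }
    gain_i <- (!is.na(cell_ratio) &&
                 cell_ratio > params$gain_ratio_threshold) ||
      t > params$gain_signals_per_cell
    if (gain_i) n_cell_gain <- n_cell_gain + 1
    if (!is.na(cell_ratio) && cell_ratio < params$deletion_ratio_threshold) {
      n_cell_del <- n_cell_del + 1
    }
  }
  ratio <- tot_t / ((tot_r + tot_g) / 2)
  mean_signals <- mean(cells$test_count)
  status <- if (ratio > params$gain_ratio_threshold ||
                mean_signals > params$gain_signals_per_cell) {
    "gain"
  } else if (ratio < params$deletion_ratio_threshold ||
             n_cell_del / n > params$heterogeneity_fraction) {
    "deleted"
  } else {
    "no_gain"
  }
  frac_gain <- n_cell_gain / n
  list(status = status,
       heterogeneous = min(frac_gain, 1 - frac_gain) >=
         params$heterogeneity_fraction)
}

# Random cell table exercising all scoring branches (gains, deletions,
# zero-control cells, sub-minimum cell counts).
random_measurement <- function() {
  n <- sample(30:120, 1)
  mean_t <- sample(c(0.8, 1, 2, 2.5, 3.5, 5.5), 1)
  cells <- data.frame(
    test_count = rpois(n, mean_t),
    control_red_count = rpois(n, 2),
    control_green_count = rpois(n, 2)
  )
  # occasionally blank both controls in a few cells
  if (runif(1) < 0.3) {
    k <- sample(seq_len(n), max(1, n %/% 20))
    cells$control_red_count[k] <- 0L
    cells$control_green_count[k] <- 0L
  }
  cells
}

# Penalized logistic objective as glmnet defines it:
# (1/n) * negative log-likelihood + lambda * sum(|beta|), intercept free.
l1_objective <- function(b, x, y, lambda) {
  eta <- b[1] + x %*% b[-1]
  -mean(y * eta - log1p(exp(eta))) + lambda * sum(abs(b[-1]))
}

# Coarse-to-fine grid search over (intercept, beta1, beta2).
oracle_l1_fit <- function(x, y, lambda, center = c(0, 0, 0),
                          width = 4, rounds = 8, pts = 13) {
  best <- center
  for (r in seq_len(rounds)) {
    grids <- lapply(best, function(c0) seq(c0 - width, c0 + width,
                                           length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, l1_objective, x = x, y = y, lambda = lambda)
    best <- cand[which.min(vals), ]
    width <- width * 2.5 / (pts - 1)  # shrink around the incumbent
  }
  # snap near-zero slopes onto the kink of the |.| penalty
  for (j in 2:3) {
    b0 <- best; b0[j] <- 0
    if (l1_objective(b0, x, y, lambda) <=
        l1_objective(best, x, y, lambda)) best <- b0
  }
  unname(best)
}

# Complete the sample-locus grid for a cohort's cell table.
full_grid <- function(cohort, loci = FISH_LOCI) {
  expand.grid(sample_id = cohort$samples$sample_id, locus = loci,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
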