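make_cells <- function(test, red = 2, green = 2, n = length(test)) {
  data.frame(test_count = rep_len(test, n),
             control_red_count = rep_len(red, n),
             control_green_count = rep_len(green, n))
}

test_that("sample_ratio pools the two control totals by averaging", {
  expect_equal(sample_ratio(make_cells(2, n = 10)), 1.0)
  expect_equal(sample_ratio(make_cells(4, n = 10)), 2.0)
  cells <- data.frame(test_count = c(3, 3, 2),
                      control_red_count = c(2, 2, 1),
                      control_green_count = c(2, 2, 3))
  expect_equal(sample_ratio(cells), 8 / 6)
  expect_error(sample_ratio(make_cells(2, red = 0, green = 0, n = 5)),
               "ratio undefined")
})

test_that("per-cell status follows the ratio and signal-count rules", {
  cells <- data.frame(test_count = c(4, 1, 2, 9, 2),
                      control_red_count = c(2, 2, 2, 0, 0),
                      control_green_count = c(2, 2, 2, 0, 0))
  # 9 signals with no controls: only the >3-signals rule applies
  expect_equal(per_cell_status(cells),
               c("gain", "deleted", "neutral", "gain", "neutral"))
})

test_that("call_locus applies cell minimum, gain and heterogeneity rules", {
  p <- call_params()
  # below the 40-cell minimum
  low_n <- call_locus(make_cells(4, n = 30), p)
  expect_equal(low_n$status, "no_signal")
  expect_true(is.na(low_n$ratio) && is.na(low_n$mean_signals_per_cell))
  expect_equal(low_n$n_cells_scored, 30)
  # clean gain
  gained <- call_locus(make_cells(4, n = 100), p)
  expect_equal(gained$status, "gain")
  expect_false(gained$heterogeneous)
  expect_equal(gained$ratio, 2.0)
  # mixed population right at the rule boundaries: pooled ratio
  # (70*2 + 30*5)/200 = 1.45 <= 1.5 and mean signals 2.9 <= 3 -> no_gain,
  # but 30% of cells are individually gain-called -> heterogeneous
  mixed <- rbind(make_cells(2, n = 70), make_cells(5, n = 30))
  res <- call_locus(mixed, p)
  expect_equal(res$status, "no_gain")
  expect_true(res$heterogeneous)
  expect_equal(res$ratio, 1.45)
  expect_equal(res$mean_signals_per_cell, 2.9)
})

test_that("thresholds are strict: sitting exactly on them does not trigger", {
  # ratio exactly 1.5: test 3 vs controls 2/2
  expect_equal(call_locus(make_cells(3, n = 50))$status, "no_gain")
  # mean signals exactly 3 (ratio 1.5 too)
  expect_equal(call_locus(make_cells(3, n = 40))$status, "no_gain")
  # ratio exactly 0.75: test 3 vs controls 4/4
  expect_equal(call_locus(make_cells(3, red = 4, green = 4, n = 50))$status,
               "no_gain")
  # just over/under the boundaries
  just_over <- rbind(make_cells(2, red = 1, green = 1, n = 26),
                     make_cells(1, red = 1, green = 1, n = 24))
  expect_equal(sample_ratio(just_over), 1.52)
  expect_lt(call_locus(just_over)$mean_signals_per_cell, 3)
  expect_equal(call_locus(just_over)$status, "gain")
  just_under <- rbind(make_cells(2, red = 3, green = 3, n = 10),
                      make_cells(3, red = 4, green = 4, n = 40))
  expect_equal(sample_ratio(just_under), 140 / 190)  # 0.737 < 0.75
  expect_equal(call_locus(just_under)$status, "deleted")
  # exactly 40 cells is evaluable, 39 is not
  expect_equal(call_locus(make_cells(4, n = 40))$status, "gain")
  expect_equal(call_locus(make_cells(4, n = 39))$status, "no_signal")
})

test_that("deletion is called by pooled ratio or by the cell-fraction rule", {
  expect_equal(call_locus(make_cells(1, n = 60))$status, "deleted")
  # pooled ratio fine but >25% of cells individually deleted
  mixed <- rbind(make_cells(1, n = 16), make_cells(3, n = 44))
  expect_equal(sample_ratio(mixed) > 0.75, TRUE)
  expect_equal(call_locus(mixed)$status, "deleted")
  # exactly 25% of cells deleted does not trigger (strict)
  mixed25 <- rbind(make_cells(1, n = 15), make_cells(3, n = 45))
  expect_equal(call_locus(mixed25)$status, "no_gain")
})

test_that("gain takes precedence over deletion when both rules fire", {
  # 30% of cells deleted (fraction rule) but high-signal cells push the
  # mean over 3: (1*18 + 6*42)/60 = 4.5
  cells <- rbind(make_cells(1, n = 18), make_cells(6, n = 42))
  res <- call_locus(cells)
  expect_gt(res$mean_signals_per_cell, 3)
  expect_equal(res$status, "gain")
})

test_that("monotonicity: raising test counts never drops a gain call", {
  set.seed(41)
  for (rep in 1:50) {
    cells <- random_measurement()
    base <- call_locus(cells)
    i <- sample(nrow(cells), 1)
    up <- cells; up$test_count[i] <- up$test_count[i] + 1L
    res <- call_locus(up)
    if (base$status == "gain") expect_equal(res$status, "gain")
    down <- cells
    down$test_count[i] <- max(0L, down$test_count[i] - 1L)
    res2 <- call_locus(down)
    if (base$status == "deleted") expect_equal(res2$status, "deleted")
  }
})

test_that("ratio is invariant to scaling every count by a constant", {
  set.seed(42)
  for (rep in 1:20) {
    cells <- random_measurement()
    for (k in c(2L, 5L)) {
      scaled <- cells
      scaled[] <- lapply(scaled, function(v) v * k)
      expect_equal(sample_ratio(scaled), sample_ratio(cells))
    }
  }
})

test_that("vectorized caller agrees with call_locus and the rule oracle", {
  set.seed(43)
  n_meas <- 300
  tables <- replicate(n_meas, random_measurement(), simplify = FALSE)
  cells <- do.call(rbind, Map(function(tb, i) {
    cbind(sample_id = sprintf("m%03d", i), locus = "1q", tb)
  }, tables, seq_len(n_meas)))
  grid <- data.frame(sample_id = sprintf("m%03d", seq_len(n_meas)),
                     locus = "1q")
  vec <- call_loci(cells, grid = grid)
  for (i in seq_len(n_meas)) {
    one <- call_locus(tables[[i]])
    ora <- oracle_call_locus(tables[[i]])
    expect_equal(vec$status[i], one$status)
    expect_equal(vec$status[i], ora$status)
    expect_equal(vec$heterogeneous[i], ora$heterogeneous)
    if (!is.na(one$ratio)) expect_equal(vec$ratio[i], one$ratio)
  }
})

test_that("missing sample-locus pairs in the grid are no_signal calls", {
  cells <- cbind(sample_id = "s1", locus = "1q", make_cells(4, n = 50))
  grid <- data.frame(sample_id = c("s1", "s1", "s2"),
                     locus = c("1q", "8q24", "1q"))
  calls <- call_loci(cells, grid = grid)
  expect_equal(calls$status, c("gain", "no_signal", "no_signal"))
  expect_equal(calls$n_cells_scored, c(50L, 0L, 0L))
})

test_that("negative or non-integer counts are rejected", {
  bad <- make_cells(2, n = 45)
  bad$test_count[3] <- -1L
  expect_error(call_locus(bad), "nonnegative integer")
  expect_error(sample_ratio(transform(make_cells(2, n = 5),
                                      control_red_count = 1.5)),
               "nonnegative integer")
})
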