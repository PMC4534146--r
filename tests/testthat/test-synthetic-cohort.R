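test_that("deterministic noise with zero dropout reproduces true copies", {
  det <- noise_model("deterministic", dropout_prob = 0)
  cells <- generate_cell_signals(locus_state("disomy"), 100, det)
  expect_equal(nrow(cells), 100)
  expect_true(all(cells$test_count == 2))
  expect_true(all(cells$control_red_count == 2))
  expect_true(all(cells$control_green_count == 2))
  # assay failure yields no cells
  expect_equal(nrow(generate_cell_signals(locus_state("assay_failure"), 80,
                                          det)), 0)
  expect_error(locus_state("nonsense"), "invalid state label")
})

test_that("poisson counts have the configured mean (law of large numbers)", {
  cells <- generate_cell_signals(locus_state("low_gain", mean_test_copies = 4),
                                 10000, noise_model("poisson"), rng_seed = 51)
  se <- sqrt(4 / 10000)
  expect_lt(abs(mean(cells$test_count) - 4), 3 * se)
  # binomial dropout thins the mean
  thinned <- generate_cell_signals(
    locus_state("low_gain", mean_test_copies = 4), 10000,
    noise_model("poisson", dropout_prob = 0.25), rng_seed = 52)
  expect_lt(abs(mean(thinned$test_count) - 3), 3 * sqrt(3 / 10000))
})

test_that("heterogeneous gains split cells between subclone and disomy", {
  st <- locus_state("heterogeneous_gain", mean_test_copies = 6,
                    subclone_fraction = 0.3)
  cells <- generate_cell_signals(st, 100, noise_model("deterministic"))
  expect_equal(sum(cells$test_count == 6), 30)
  expect_equal(sum(cells$test_count == 2), 70)
  expect_error(locus_state("disomy", subclone_fraction = 0.5),
               "only applies")
})

test_that("an all-disomy deterministic cohort calls no_gain everywhere", {
  probs <- lapply(c("1q", "8q24", "11q13", "HER2"),
                  function(l) c(disomy = 1))
  names(probs) <- c("1q", "8q24", "11q13", "HER2")
  cfg <- cohort_config(n_dcis_only = 10, n_dcis_ibc = 10,
                       state_probs = list(dcis_only = probs,
                                          dcis_ibc = probs),
                       noise = noise_model("deterministic"), seed = 5)
  co <- generate_cohort(cfg)
  calls <- call_loci(co$cells, grid = full_grid(co))
  expect_true(all(calls$status == "no_gain"))
  pr <- build_profiles(calls)
  expect_true(all(pr$gain_category == "no_gains"))
})

test_that("empty cohort generation and round trip work", {
  cfg <- cohort_config(n_dcis_only = 0, n_dcis_ibc = 0, seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$samples), 0)
  expect_equal(nrow(co$cells), 0)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$samples), 0)
  expect_equal(nrow(back$cells), 0)
})

test_that("cohorts are deterministic in the seed and differ across seeds", {
  cfg <- cohort_config(n_dcis_only = 30, n_dcis_ibc = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_dcis_only = 30, n_dcis_ibc = 30,
                                      seed = 100))
  expect_false(identical(a$cells$test_count, c2$cells$test_count))
})

test_that("write/read round trip is the identity", {
  co <- generate_cohort(cohort_config(n_dcis_only = 25, n_dcis_ibc = 25,
                                      seed = 7))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$samples, co$samples)
  expect_equal(back$cells, co$cells)
})

test_that("malformed cell files are rejected with the offending line", {
  co <- generate_cohort(cohort_config(n_dcis_only = 5, n_dcis_ibc = 5,
                                      seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  cells$test_count[4] <- -2
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "line 5.*test_count")
})

test_that("state probabilities must sum to one", {
  probs <- default_state_probs()
  probs$dcis_only$`1q`["disomy"] <- probs$dcis_only$`1q`["disomy"] + 0.05
  expect_error(cohort_config(state_probs = probs), "sum to")
})

test_that("called gain frequencies track the configured state frequencies", {
  n <- 1200
  co <- generate_cohort(cohort_config(n_dcis_only = n, n_dcis_ibc = n,
                                      seed = 77))
  calls <- call_loci(co$cells, grid = full_grid(co))
  pr <- build_profiles(calls)
  g <- co$samples$group[match(pr$sample_id, co$samples$sample_id)]
  sp <- default_state_probs()
  for (grp in c("dcis_only", "dcis_ibc")) {
    for (loc in FISH_LOCI) {
      conf <- sp[[grp]][[loc]]
      target <- unname(conf[["low_gain"]] + conf[["high_gain"]])
      emp <- mean(pr[[paste0("status_", loc)]][g == grp] == "gain")
      half_width <- qnorm(0.995) * sqrt(target * (1 - target) / n)
      expect_lt(abs(emp - target), half_width + 1e-12)
      target_ns <- unname(conf[["assay_failure"]])
      emp_ns <- mean(pr[[paste0("status_", loc)]][g == grp] == "no_signal")
      expect_lt(abs(emp_ns - target_ns),
                qnorm(0.995) * sqrt(target_ns * (1 - target_ns) / n) + 1e-12)
    }
  }
})

test_that("logistic link recovers the configured all-three odds ratio", {
  cfg <- cohort_config(n_dcis_only = 5000, n_dcis_ibc = 5000,
                       link_mode = "logistic_link", seed = 55)
  co <- generate_cohort(cfg)
  calls <- call_loci(co$cells, grid = full_grid(co))
  pr <- build_profiles(calls)
  tab <- tabulate_categories(pr, co$samples$group)
  u <- univariate_category_or(tab)
  all3 <- u[u$category == "all_three", ]
  expect_gt(7.04, all3$ci_low)
  expect_lt(7.04, all3$ci_high)
  two3 <- u[u$category == "two_of_three", ]
  expect_gt(5.70, two3$ci_low)
  expect_lt(5.70, two3$ci_high)
})
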