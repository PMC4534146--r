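---
title: "Copy-number gain scoring and invasive-cancer risk in DCIS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number gain scoring and invasive-cancer risk in DCIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisgain)
```

## The problem

Ductal carcinoma in situ (DCIS) is a noninvasive breast neoplasm whose
management hinges on an unanswered question: which lesions are associated
with, or will progress to, invasive breast cancer (IBC)? Chromosomal
copy-number gains accumulate early in breast tumorigenesis and can be
measured in routine pathology material by fluorescence in situ
hybridization (FISH). This package implements a complete analysis pipeline
for a four-locus FISH panel — the risk loci 1q, 8q24 and 11q13 plus HER2
(17q12) — scored on DCIS cells from a case–control design (DCIS with
concurrent IBC versus DCIS alone):

1. per-cell probe signal counts → a categorical per-locus call
   (`fish_caller` functions);
2. per-locus calls → per-sample gain combinations and a mutually exclusive
   six-level gain category (`gain_profiles` functions);
3. marker combinations vs the IBC label → sensitivity, specificity,
   predictive values and exact Fisher tests (`diagnostics` functions);
4. gain category and covariates vs IBC → Wald odds ratios and a
   complete-case multivariable logistic model (`association` functions);
5. a stand-alone simulation experiment asking which classes of genomic
   alterations (by population frequency and case/control differential) are
   selected by a cross-validated L1-logistic predictor
   (`predictor_simulation` functions).

Because the study's raw tissue-microarray data are not publicly available,
a synthetic cohort generator reproduces the statistical structure the
pipeline assumes, so every stage is exercised end to end; the published
contingency counts are shipped as plain-CSV fixtures and drive the
table-reproduction analyses.

## FISH scoring model

For one sample-locus, each scored cell carries three nonnegative integer
counts: the test-probe signals and the two control-probe signals (3q25,
2q37). The sample-level decision statistic is the pooled ratio

$$ R \;=\; \frac{\sum_i t_i}{\tfrac12\left(\sum_i r_i + \sum_i g_i\right)} $$

and the call is:

* **no_signal** if fewer than 40 cells were scored (`min_cells`);
* **gain** if $R > 1.5$ or the mean test signals per cell exceed 3;
* **deleted** if $R < 0.75$, or if more than 25% of scored cells
  individually have a cell-level ratio below 0.75;
* **no_gain** otherwise; gain takes precedence when rules conflict.

A sample is flagged **heterogeneous** when the minority side of the
per-cell gain/non-gain partition holds at least 25% of cells. All
thresholds are strict inequalities: a ratio of exactly 1.5 is not a gain
and exactly 0.75 is not a deletion, and these boundaries are pinned by
tests.

Design choices where the scoring convention is genuinely open:

* **Control pooling.** The two control probes are combined by averaging
  their totals into one denominator. A strict mode
  (`call_params(pool_controls = "strict")`) instead requires the ratio
  criterion against each control separately; the default is the pooled
  form because a single decision ratio matches how dual-control FISH
  ratios are reported in practice.
* **"More than three signals per cell"** is read at the sample level as
  mean test signals per scored cell > 3; the per-cell version of the rule
  feeds only the per-cell statuses used for heterogeneity.
* **Cells with zero counts in both controls** carry no ratio information:
  they are excluded from all ratio-based rules (including the pooled
  totals) but still count toward the signals-per-cell rule and the cell
  total.
* **Heterogeneity** is computed on the gain/non-gain partition of per-cell
  statuses, the simplest reading of "a different signal call".

## Combinations, categories and tables

A combination of loci is `yes` when every member is gained, `no_signal`
when any member is unevaluable, `no` otherwise. The mutually exclusive
six-level category uses only the three risk loci: `unable_to_determine`
when any of them is `no_signal`, otherwise `no_gains`, one of the three
single-gain levels, `two_of_three`, or `all_three`. Deleted calls count as
not gained, and HER2 never enters the category — it participates only in
requested combinations and as a covariate.

Prevalence tables report counts by diagnosis group with two percentage
conventions: percent of the group total, and percent of signal-evaluable
samples (`yes / (yes + no)`), which is the convention behind the headline
gain frequencies (1q 52%, 8q24 44%, HER2 32.9%).

Diagnostic performance treats a combination as a binary marker against the
IBC label, excluding unevaluable samples (so each marker has its own
table total). The two-tailed Fisher test is an exact hypergeometric
enumeration using the probability-mass rule — the p value sums all tables
with fixed margins whose point probability does not exceed the observed
table's (relative tolerance 1e-7, the convention of mainstream statistical
software); a zero margin returns p = 1 by convention. No continuity
corrections are used anywhere.

## Odds ratios and the logistic model

Univariate odds ratios per gain category are cross-product ratios against
the `no_gains` reference with Wald confidence intervals,
$\exp(\log\mathrm{OR} \pm 1.96\,\mathrm{SE})$,
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$. Zero cells raise an error by
default; a Haldane–Anscombe +0.5 mode is available behind a flag. Wald
(rather than profile-likelihood) intervals are used because they exactly
reproduce the published univariate column, including the all-three
interval (2.16, 23.00), from the published category counts.

The multivariable model regresses IBC on gain category, age group, race
(collapsed to NH white / NH Asian-Pacific Islander / other), hormone
receptor status, grade and HER2 gain, on complete cases only (missing any
model variable, or an undeterminable category, excludes the sample).
`fit_logistic()` is an explicit IRLS implementation: convergence when the
largest absolute coefficient change falls below 1e-8 (at most 100
iterations), step-halving so the log-likelihood trace is monotone
non-decreasing, rank-deficiency reported with the collinear column names,
and divergence toward separation flagged as `converged = FALSE` with a
diagnostic rather than an error. Reference levels are fixed in
`model_spec()` (no_gains, age 50–64, race other, ER/PR positive, grade 1,
HER2 no). Multi-degree-of-freedom term tests are Wald chi-square on the
fitted covariance.

Two published quantities are deliberately **not** reproduced: the
multiple-imputation column (a Stata `mi impute chained` analysis outside
this package's scope) and the printed multivariable odds ratios (9.07,
17.96, ...), which depend on the study's raw patient-level covariates.
The multivariable machinery is instead validated by synthetic parameter
recovery: cohorts generated with known log-odds are re-fitted and the Wald
intervals attain nominal coverage.

## The synthetic cohort generator

The generator emulates exactly the structure the pipeline consumes.

* **Latent states.** Each sample-locus draws a state: disomy (mean 2 test
  copies), low gain (3.5), high gain (5.5), deletion (1), heterogeneous
  gain (subclone at mean 4), or assay failure (no scored cells). Default
  state probabilities per group and locus are taken from the published
  per-locus no-signal/no/yes fractions, with the gained mass split between
  low and high gains using the published proportions (1q 80/20, 8q24
  78/22, 11q13 53/47; HER2 is unpublished and uses 80/20).
* **Counts.** Per-cell counts are Poisson around the true mean with
  optional per-signal binomial dropout; control probes are independent
  Poisson with mean 2. A deterministic mode yields exact rounded copies
  and, with zero dropout, reproduces true copy numbers cell for cell. The
  Poisson choice is the simplest integer-count model that exercises every
  scoring branch.
* **Correlated assay failures.** Real tissue-microarray failures cluster
  within a core: the published no-signal counts give a three-locus union
  of 40% against per-locus marginals of 22–29%, far below the ~59% an
  independent model implies. A per-sample core-failure indicator (default
  probability 0.17) therefore couples failures across loci while
  preserving each locus's marginal failure probability; 0.17 reproduces
  the published ~60% of samples determinable at all three loci. HER2,
  which has no published failures, is untouched.
* **Covariates** are drawn independently from the published per-group
  marginals, including their missingness mass, which together with the
  determinable rate yields roughly 56% complete cases — the published
  complete-case fraction (158/280).
* **Two linkage modes.** `state_first` fixes each sample's group and draws
  states from that group's distribution (matching the published
  prevalence tables). `logistic_link` draws states from the control
  distribution for everyone and then assigns the group label by a
  logistic model on the sample's *called* category, with offsets
  defaulting to the published univariate log-odds — making the logistic
  model exactly true by construction, which is what parameter-recovery
  tests require.
* **Seeding.** One master seed spawns fixed per-stage substreams; the same
  configuration and seed reproduce a cohort byte for byte.

What the generator does **not** model: spatial tissue structure, probe
hybridization chemistry, image segmentation, within-patient correlation
between multiple samples of one patient (the study treated samples as the
unit and addressed multi-sample patients in a sensitivity analysis), or
correlation between covariates. Passing tests therefore demonstrate that
the pipeline's statistics behave correctly under the stated sampling
model, not that the scoring rules are robust to imaging artifacts. One
visible artifact of the Poisson noise: per-cell statuses are noisy enough
that the 25% heterogeneity flag fires for most evaluable sample-loci; the
flag does not feed any downstream table, and the sample-level gain calls
remain accurate because they pool over 40–100 cells.

## The predictor simulation experiment

The experiment asks which kinds of genomic alterations would carry a
genomic predictor of IBC risk in DCIS. Twenty-two independent binary
features are classed by population frequency — low (5%), mid (15%), high
(30%), with 10/6/6 features respectively — and by case/control
differential — nondifferential, or folds of 1.25 (LD), 1.5 (MD) and 3.0
(HD), with exactly one differential feature per frequency × {LD, MD, HD}
cell. Case frequency is fold × base capped at 1, anchored on the control
frequency (the direct reading of "X-fold higher in cases versus
controls"). Each iteration simulates 151 cases and 129 controls, fits an
L1-regularized logistic predictor, and records the active features and
the held-out AUC.

Numerical choices:

* The lambda path is fitted by glmnet's cyclic coordinate descent with
  soft-thresholding, intercept unpenalized and no standardization (the
  features are binary on a common scale). The package's own code derives
  the grid — 50 log-spaced values from the data-derived
  $\lambda_{\max} = \max_j |x_j'(y - \bar y)|/n$ down to
  $\lambda_{\max}/1000$ — and owns fold assignment, lambda selection and
  scoring; a brute-force penalized-likelihood grid search is the
  independent oracle for the solver in the test suite.
* Folds are stratified by label with seeded shuffling.
* Lambda is selected by maximum mean per-fold held-out AUC (ties resolve
  to the larger, sparser lambda); a minimum-deviance alternative is
  available via `sim_design(selection = "deviance")`. The selection rule
  of the original experiment is unstated; the reported low-frequency
  highly-differential proportion is tolerance-banded accordingly.
* The reported held-out AUC at the selected lambda is computed on pooled
  out-of-fold predictions (midrank Mann–Whitney AUC, so constant
  predictions give exactly 0.5).
* A class is "active" in an iteration when any of its features has a
  nonzero coefficient in the full-data refit at the selected lambda. The
  nine differential cells hold one feature each; nondifferential cells
  hold several, so cross-class comparisons involving ND cells are made on
  the per-feature scale in the tests.

Under the default design the moderate- and high-frequency highly
differential classes are active in ≥ 99% of iterations while the
low-frequency highly differential class is active in roughly two-thirds —
the frequency of an alteration, not only its effect size, determines its
usefulness in a risk predictor of this sample size.

## Problem sizes used by the shipped checks

The test suite exercises: the full enumeration of Fisher tables up to
total 40; 1000 random measurements against a rule-by-rule scoring oracle;
500-iteration simulation runs for the selection-proportion findings;
200-replicate parameter-recovery runs at 2500 samples per replicate
(three-locus panel) for Wald coverage; and 10000-sample binomial checks
for the generator's marginals. The acceptance script runs the full
2000-iteration experiment. These sizes are the package's own choices,
balancing the tightness of the statistical bands against a test run of a
few minutes.

## Known limitations

* The univariate odds ratios are computed on samples (n = 280), not
  patients (n = 271); the exact reproduction of the published univariate
  column from the published sample counts indicates that convention.
* Published inconsistencies are shipped verbatim but excluded from
  derived analyses: the 8q24+11q13+HER2 combination row lacks a `yes`
  line and carries a no-signal count inconsistent with its member loci,
  and the headline 11q13 frequency (20%) does not match its own printed
  counts (30.6% of evaluable samples).
* Fisher tests and Wald intervals are unconditional on the calling
  pipeline: uncertainty in the per-locus calls themselves (cell sampling
  noise) is not propagated into the downstream tables, mirroring the
  original analysis.
* The logistic-link generator conditions group labels on *called* (not
  latent) categories; recovery tests therefore validate estimation, not
  robustness to call misclassification.
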