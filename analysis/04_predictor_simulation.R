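#!/usr/bin/env Rscript
# The genomic-predictor simulation experiment: which alteration classes
# (population frequency x case/control differential) end up as active
# features of a cross-validated L1-logistic predictor of invasive cancer.
#
# Usage: Rscript analysis/04_predictor_simulation.R [n_iterations] [seed]
# Defaults to 500 iterations; 2000 reproduces the full-scale experiment.

suppressMessages(library(dcisgain))
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
n_iter <- if (length(args) >= 1) as.integer(args[1]) else 500L
seed <- if (length(args) >= 2) as.integer(args[2]) else 42L

design <- sim_design(n_iterations = n_iter, seed = seed)
cat(sprintf("running %d iterations (%d cases vs %d controls, %d features)...\n",
            n_iter, design$n_cases, design$n_controls,
            nrow(design$features)))
summary <- run_simulation(design, progress = TRUE)
print(summary)

write_sim_summary(summary, "results/sim_summary.json")
write.csv(summary$iterations, "results/sim_iterations.csv",
          row.names = FALSE)

sp <- summary$selection_proportion
cat(sprintf("\nheadline: MFxHD %.1f%%, HFxHD %.1f%%, LFxHD %.1f%%\n",
            100 * sp$selection_proportion[sp$class == "MFxHD"],
            100 * sp$selection_proportion[sp$class == "HFxHD"],
            100 * sp$selection_proportion[sp$class == "LFxHD"]))

# bar chart of per-class selection proportions
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  sp$freq_class <- factor(sp$freq_class, c("LF", "MF", "HF"))
  sp$diff_class <- factor(sp$diff_class, c("ND", "LD", "MD", "HD"))
  gg <- ggplot(sp, aes(diff_class, selection_proportion,
                       fill = freq_class)) +
    geom_col(position = position_dodge()) +
    labs(x = "case/control differential class",
         y = "proportion of iterations with the class active",
         fill = "frequency class") +
    theme_minimal()
  ggsave("results/selection_proportions.png", gg, width = 7, height = 4,
         dpi = 150)
  cat("wrote results/selection_proportions.png\n")
}
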