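#!/usr/bin/env Rscript
# Robustness of the full model on the abundant-signal preset: retrain
# after (a) removing training peptides similar to the cognate at identity
# thresholds 6..2 and (b) downsampling the training set, re-ranking the
# cognate each time.

suppressPackageStartupMessages(library(epibind))
dir.create("results", showWarnings = FALSE)

seed <- 1L
sim <- simulate_preset("abundant-signal", n_peptides = 30000L, seed = seed)
cfg <- model_config(weighting = TRUE, shifting = TRUE, composition = TRUE,
                    epochs = 10L, seed = seed + 37L)
rob <- run_robustness_suite(sim$binding_table, sim$cognate, config = cfg,
                            thresholds = c(6L, 5L, 4L, 3L, 2L),
                            fractions = c(1, 0.5, 0.25, 0.12, 0.06),
                            n_models = 1L, n_random = 5e4, seed = seed)
cat("similarity filtering:\n")
print(rob$similarity, row.names = FALSE)
cat("downsampling:\n")
print(rob$downsampling, row.names = FALSE)
write.table(rob$similarity, "results/robustness_similarity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rob$downsampling, "results/robustness_downsampling.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote robustness tables under results/\n")
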