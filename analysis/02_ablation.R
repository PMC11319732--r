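#!/usr/bin/env Rscript
# Run the cumulative ablation ladder (baseline -> +weighting -> +shifting
# -> +composition) on both synthetic presets and tabulate the cognate's
# rank among random sequences at each stage.
#
# Expect the abundant regime to rank well from the baseline on, and the
# scarce regime to depend strongly on weighting + shifting.

suppressPackageStartupMessages(library(epibind))
dir.create("results", showWarnings = FALSE)

seed <- 1L
cfg <- model_config(epochs = 10L, seed = seed)

for (preset in c("abundant-signal", "scarce-signal")) {
  cat("==", preset, "==\n")
  sim <- simulate_preset(preset, n_peptides = 30000L, seed = seed)
  lad <- run_ablation_ladder(sim$binding_table, sim$cognate, config = cfg,
                             n_models = 2L, n_random = 5e4, seed = seed)
  print(lad[c("stage", "mean_rank", "sem", "percent_rank")],
        row.names = FALSE)
  tag <- sub("-signal", "", preset)
  write.table(lad, file.path("results", paste0("ablation_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote ablation tables under results/\n")
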