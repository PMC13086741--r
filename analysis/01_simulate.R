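#!/usr/bin/env Rscript

# Stage 1: generate the three per-tissue datasets the downstream stages
# analyse. Each tissue gets an independent single-tissue dataset with the
# emulated design (3 treatments x 10 replicates) and a planted mixture of
# gene classes, so the later stages can be scored against known truth:
#   2% unique to positive training, 2% unique to negative training,
#   1% shared same-direction (learning), 2% antagonistic (valence),
#   the rest null. Effects are |log2FC| = 2 at NB dispersion 0.2.

suppressPackageStartupMessages(library(valenceDE))

out_root <- "results/data"
tissues <- c(antennae = 101L, eyes = 102L, brain = 103L)

for (tissue in names(tissues)) {
  cfg <- sim_config(
    n_genes = 3000, n_reps_per_treatment = 10, tissue = tissue,
    dispersion = 0.2, effect_lfc = 2,
    frac_unique_pos = 0.02, frac_unique_neg = 0.02,
    frac_shared_learning = 0.01, frac_antagonistic = 0.02,
    seed = tissues[[tissue]]
  )
  dataset <- simulate_counts(cfg)
  paths <- write_dataset(dataset, file.path(out_root, tissue))
  n_planted <- sum(dataset$truth$class != "null")
  message(sprintf("%s: %d genes x %d samples, %d planted non-null genes -> %s",
                  tissue, nrow(dataset$counts), ncol(dataset$counts),
                  n_planted, dirname(paths[["counts"]])))
}
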