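#!/usr/bin/env Rscript
# Generate the default synthetic study: 1,000 promoters (50 DE), 50 TF
# motifs (5 transcriptionally active, planted at rate 0.8 in DE promoters vs
# 0.1 elsewhere), a focal promoter carrying 8 TF sites, an expression table
# with negative-control probes, and the 26-sample four-group miRNA/target
# table with 5-fold induction at 10 days.

library(tfbscreen)

seed <- 1L
cfg <- scenario_config(seed = seed)
scen <- generate_scenario(cfg, dir = "results/data")

cat("Scenario written to results/data (seed ", seed, ")\n", sep = "")
cat("  genes:", length(scen$universe), " (DE:", length(scen$de_genes), ")\n")
cat("  TFs:", length(scen$motifs),
    " active:", paste(cfg$active_tfs, collapse = ", "), "\n")
cat("  focal TFs:", paste(cfg$focal_tfs, collapse = ", "), "\n")
cat("  silent TFs:", paste(cfg$silent_tfs, collapse = ", "), "\n")
cat("  expected final candidates:",
    paste(scen$truth$expected_candidates, collapse = ", "), "\n")
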