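#!/usr/bin/env Rscript
# Resampling enrichment: for each TF, compare its observed motif-hit total
# over the DE promoters with the distribution over 10,000 random gene sets
# of the same size, report empirical p-values, ranks and significance tiers.

library(tfbscreen)

counts <- read_hit_counts("results/hit_counts.tsv")
genes <- gene_list(read_gene_list("results/data/de_genes.txt"),
                   read_gene_list("results/data/universe.txt"))

enr <- enrich_tfs(counts, genes, n_resamples = 10000L, seed = 1L)
write_enrichment(enr, "results/enrichment.tsv")

sig <- enr[enr$p_empirical < 0.05, ]
cat("TFs significantly enriched (raw p < 0.05):", nrow(sig), "of",
    nrow(enr), "\n")
print(sig[, c("tf_id", "observed", "null_mean", "p_empirical", "tier")],
      row.names = FALSE)
cat("Full table written to results/enrichment.tsv\n")
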