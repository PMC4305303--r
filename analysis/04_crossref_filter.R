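#!/usr/bin/env Rscript
# Candidate triage: intersect the enrichment-significant TFs with TFs that
# have predicted sites in the focal (miRNA cluster) promoter, then drop
# candidates whose array expression does not clear the negative-control
# floor (mean + 2 SD of the negative-control probes).

library(tfbscreen)

enr <- utils::read.delim("results/enrichment.tsv")
motifs <- read_jaspar("results/data/motifs.jaspar")
pwms <- lapply(motifs, pwm_from_counts)
focal_seq <- read_promoters("results/data/focal.fasta")[[1]]
expr <- read_expression("results/data/expression.tsv")

focal_set <- focal_promoter_tfs(pwms, focal_seq, rel_threshold = 0.8)
out <- crossref_candidates(enr, focal_set, expr, alpha = 0.05, k_sd = 2)
utils::write.table(out$table, "results/candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Venn: enriched-only", length(out$enriched_only),
    "| both", length(out$both),
    "| focal-only", length(out$focal_only), "\n")
cat("Expression filter kept", length(out$expressed_pass), "of",
    length(out$both), "intersection TFs\n")
cat("Final candidates (by enrichment p):",
    paste(out$final_candidates, collapse = ", "), "\n")
cat("Triage table written to results/candidates.tsv\n")
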