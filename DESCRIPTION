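Package: tfbscreen
Title: Resampling-Based Transcription Factor Motif Enrichment and
    miRNA-Target Correlation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for inferring transcriptional drivers of a
    microRNA cluster from expression changes in a perturbation model. Scans
    promoter sequences with position weight matrices, tests each transcription
    factor for binding-site enrichment in differentially expressed gene
    promoters against a gene-resampling null with empirical p-values,
    cross-references enriched factors against motifs found in a focal promoter,
    filters candidates by a negative-control expression floor, and screens
    candidate target mRNAs by regressing their fold changes on a composite
    score built from two same-seed microRNAs. Ships a synthetic-data generator
    that reproduces the statistical design of the study (four surgical groups,
    several-fold miRNA induction, inverse miRNA-target coupling, planted
    promoter motifs) so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
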