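# tfbscreen

Screening for transcriptional drivers of an induced microRNA cluster, and
for the cluster's repressed targets, from promoter sequence and expression
data.

The package grew out of a recurring analysis pattern in perturbation
studies of the miR-132/212 cluster (e.g. bladder outlet obstruction, where
the cluster is induced several-fold in the detrusor): given a list of
differentially expressed (DE) genes, which transcription factors (TFs)
were active, which of those could have driven the miRNA cluster itself,
and which validated target mRNAs track the induced miRNAs? It provides:

* **Motif scanning** — JASPAR-style PFM input, log-odds PWMs
  (pseudocount 0.25, configurable background), both-strand scanning at a
  relative score threshold
  `t = S_min + ρ (S_max − S_min)` (default ρ = 0.8), N-windows skipped.
* **Resampling enrichment** — per TF, the observed number of motif hits
  in DE-gene promoters is compared with its distribution over random
  same-size gene sets drawn from the universe; empirical p-values use the
  add-one correction `p = (1 + #{null ≥ obs}) / (1 + N)`, with ranking,
  significance tiers at raw p < 0.05 and p < 0.01, and an exact
  subset-enumeration oracle for small universes.
* **Candidate triage** — Venn intersection of enriched TFs with TFs
  having predicted sites in the focal (miRNA cluster) promoter, then a
  negative-control expression floor: a candidate survives only if its
  best probe mean exceeds `mean(NC) + k · sd(NC)` (default k = 2).
* **Composite-miRNA target screen** — the two same-seed miRNAs are each
  normalized to their sham-group mean and summed (sham mean of the
  composite is exactly 2); each candidate target's fold change is
  regressed on the composite by OLS with the two-sided t test of zero
  slope; targets with p < 0.05 and negative slope are called inversely
  coupled.
* **A synthetic-data generator** — four-group design (sham, obstructed
  10 d, obstructed 6 wk, de-obstructed; 26 samples), several-fold miRNA
  induction, planted promoter motifs for "active" TFs, a focal promoter
  with known sites, negative-control probes, and a machine-readable truth
  record, so the whole chain runs and is tested without external data.

The methods vignette (`vignettes/tfbscreen-methods.Rmd`) documents the
model, the defaults and the design decisions.

## Worked example

The numbered scripts under `analysis/` run the default synthetic study end
to end, writing tables under `results/`:

```sh
Rscript analysis/01_generate_data.R
Rscript analysis/02_scan_promoters.R
Rscript analysis/03_enrichment.R
Rscript analysis/04_crossref_filter.R
Rscript analysis/05_mirna_correlation.R
```

With the default seed the generated truth plants motifs of the active TFs
TF001–TF005 in 80% of DE promoters (10% elsewhere) and gives the focal
promoter sites for TF001–TF003 plus five inactive TFs; the expected final
candidates are therefore TF001–TF003. The enrichment stage prints:

```
TFs significantly enriched (raw p < 0.05): 8 of 50
 tf_id observed null_mean p_empirical             tier
 TF002       57   18.0616  0.00009999   stringent_0.01
 TF003       78   29.5013  0.00009999   stringent_0.01
 TF004       49   20.2864  0.00009999   stringent_0.01
 TF005       65   40.9394  0.00039996   stringent_0.01
 TF039      254  221.3153  0.01549845 significant_0.05
 TF001      282  249.3745  0.01769823 significant_0.05
 TF009      122  101.6180  0.02489751 significant_0.05
 TF031      123  103.5325  0.03679632 significant_0.05
```

All five planted TFs are recovered (TF039/TF009/TF031 are borderline
chance hits at raw p < 0.05, the price of screening without multiplicity
adjustment). The triage stage intersects these with the focal-promoter
TFs and applies the expression floor, and the target screen recovers
exactly the four truly coupled targets of the nine-gene panel:

```
 gene_id       slope        r2            p direction concordant
   Ep300 -0.05801157 0.8576752 1.194769e-11   inverse       TRUE
   Mecp2 -0.08918478 0.8549263 1.505284e-11   inverse       TRUE
    Pnkd -0.05149342 0.7053673 8.086095e-08   inverse       TRUE
 Jarid1a -0.04085079 0.6712739 3.076233e-07   inverse       TRUE
```

Here `slope` is the change in target fold change per unit of the
composite miRNA score, `r2` the variance explained, and `concordant`
whether the fitted direction matches the generator's truth record. The
same run is available programmatically:

```r
library(tfbscreen)
report <- run_pipeline(default_config(seed = 1), out_dir = "results/run")
report$final_candidates
```

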