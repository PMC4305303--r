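---
title: "Inferring transcriptional drivers of a miRNA cluster: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional drivers of a miRNA cluster: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a microRNA cluster is induced by a physiological perturbation — here,
the miR-132/212 cluster in the bladder detrusor after partial outlet
obstruction — two questions follow naturally. Which transcription factors
(TFs) drove the induction? And which mRNAs did the induced miRNAs repress?
Neither can be answered by the expression data alone, but both can be
screened computationally:

1. **Drivers.** TFs that were active during the response should have their
   binding motifs over-represented in the promoters of the genes that
   changed expression. Candidate drivers of the *miRNA cluster itself*
   should additionally have predicted sites in the cluster's promoter, and
   should actually be expressed in the tissue.
2. **Targets.** Because miR-132 and miR-212 share a seed sequence, their
   combined abundance is the relevant dose; validated targets under that
   dose's control should show mRNA fold changes that decrease linearly with
   it across animals.

`tfbscreen` implements this chain as testable R functions plus thin
narrative drivers under `analysis/`: generate (or load) data, scan
promoters, test enrichment, cross-reference and filter, and screen targets.
Because the computation lives in package functions, every stage is unit- and
property-tested; the `analysis/` scripts and `run_pipeline()` only
orchestrate. No shell subcommand interface is provided — the package's
users drive it from R, and the numbered scripts are the worked analysis.

# Motif model and scanner

Motifs enter as JASPAR-style position frequency matrices (PFMs): one
non-negative count per base and motif position. A PFM of length $L$ becomes
a position weight matrix (PWM) of log-odds scores

$$
w_{b,j} = \log_2 \frac{(c_{b,j} + s)\, /\, (C_j + 4s)}{\pi_b},
$$

with counts $c_{b,j}$, column totals $C_j$, pseudocount $s$ (default 0.25
per cell) and background probabilities $\pi$ (default uniform). A window of
sequence scores $\sum_j w_{x_j, j}$; both strands are scanned (the minus
strand by reverse-complementing the matrix, which is algebraically
identical to scanning the reverse-complemented sequence), and a window is a
hit when its score reaches

$$
t = S_{\min} + \rho\,(S_{\max} - S_{\min}),
$$

the *relative score* convention with $\rho$ = `rel_threshold` (default
0.8). Overlapping and opposite-strand hits all count; windows containing N
are skipped rather than scored with a wildcard, which avoids having to
define a threshold-consistent wildcard score.

Numerical details that matter:

* Window sums are accumulated in extended precision to match R's `sum()`
  exactly, so the compiled scanner and a plain-R reference computation
  agree bit for bit (the test suite asserts equality against an
  independent brute-force scanner).
* The absolute threshold is capped at $S_{\max}$: at $\rho = 1$ the naive
  formula can land one floating-point ulp above the maximum achievable
  score and silently exclude the exact consensus.

The promoter window (default 1,000 bases) and the motif library are
deliberately pluggable inputs: different promoter definitions and motif
collections are legitimate choices, and nothing downstream depends on
them beyond the hit-count matrix.

# Resampling enrichment

For each TF the observed statistic is the total number of motif hits over
the promoters of the differentially expressed (DE) genes. Its null
distribution is obtained by drawing random gene sets of the same size,
uniformly without replacement from the measured gene universe, and
recomputing the statistic (default $N$ = 10,000 resamples; the same gene
subsets are shared across TFs, which speeds the run up without changing
any single TF's marginal null). The empirical p-value uses the add-one
correction,

$$
p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + N},
$$

one-sided in the enrichment direction, so $p \ge 1/(N+1)$ and the test is
never anti-conservative at the floor. TFs are ranked by $p$, ties broken
by the descending normal deviate $(\mathrm{obs} - \mu_0)/\sigma_0$ and
then lexically; two tiers are flagged, raw $p < 0.05$ (the headline
screen) and raw $p < 0.01$ (stringent). No multiplicity adjustment enters
the tiers — the procedure screens with raw p-values — but a
Benjamini–Hochberg q-value column is emitted as clearly supplementary
output.

Two design choices were genuinely open:

* **Counting unit.** "Number of binding motifs" is read literally as the
  total hit count; counting motif-bearing promoters instead is available
  via `statistic = "genes_with_hit"`. The total is more sensitive when
  active TFs plant several sites per promoter; the indicator variant is
  closer to a hypergeometric set test.
* **Resampling unit.** Gene sets are resampled; no GC- or length-matching
  is imposed. Since all synthetic promoters share one background
  composition this is exactly exchangeable here; on real data a matched
  background would be the cautious extension.

An exact oracle, `exact_null_enumeration()`, enumerates all
$\binom{n}{k}$ subsets when that is feasible ($\le 10^6$) and anchors the
resampling test in the suite: on a 10-gene universe with 4 DE genes every
TF's empirical p must sit within three Monte-Carlo standard errors of the
exact p.

# Candidate triage

The enrichment-significant set is intersected with the TFs that have at
least one predicted site in the focal promoter (the miRNA cluster's
promoter, supplied as a single FASTA record and scanned with the same PWMs
and threshold). The intersection is then filtered on expression: a TF
survives only if the mean of its best probe across all samples strictly
exceeds

$$
\overline{x}_{\mathrm{NC}} + k \cdot s_{\mathrm{NC}},
$$

the mean plus $k$ standard deviations (default $k$ = 2) of all
negative-control probe values pooled over probes and samples. "Expression
equal to the negative controls" has no canonical numeric form; a
detection floor at 2 SD of the no-target probes is the standard array
convention, and $k$ is exposed. TFs with no probe at all are removed and
reported as unmeasured rather than silently dropped. Final candidates are
the surviving intersection members, ordered by enrichment p-value.

# Composite miRNA score and target screen

The two cluster miRNAs share a seed, so targets see their combined dose.
Each miRNA's fold change is divided by its sham-group mean and the two
normalized values are summed, giving a composite whose sham mean is
exactly 2. The normalization makes the composite invariant to the two
miRNAs' very different absolute abundances (the second cluster member is
expressed well below the first); a z-score variant was considered and
rejected as the default because the figure being emulated plots a
fold-change-scaled axis.

Each candidate target's fold change is regressed on the composite by
ordinary least squares (`stats::lm`); the p-value is the two-sided t test
of zero slope on $n - 2$ df, reported raw per target (with a
supplementary BH column). A target is called *inverse* when $p < 0.05$
and the slope is negative, matching the screen's per-panel p-value
reporting. Fold changes are regressed on the linear scale by default;
`scale = "log2"` is available since the choice is not dictated by the
design. Degenerate inputs are contracts, not surprises: a constant
composite is an error (no design), a constant response returns slope 0,
$r^2$ = 0, $p$ = 1.

# What the synthetic data emulates

The generator reproduces the statistical skeleton of the obstruction
experiment it emulates, not its biology:

* **Design.** Four groups — sham, obstructed 10 days, obstructed 6 weeks,
  de-obstructed — with 7/7/6/6 samples (26 total), inside the typical
  6–8 animals per group of such models.
* **miRNA induction.** Group mean folds 1, 5, 3, 1.2 by default (bladder
  obstruction models show 3–7-fold miR-132/212 induction at 10 days with
  a return toward control after de-obstruction), log-normal per-sample
  noise (sdlog 0.15), both
  miRNA columns renormalized to a sham mean of exactly 1.
* **Target coupling.** A nine-gene panel of previously validated targets;
  four (Mecp2, Ep300, Pnkd, Jarid1a) are generated as
  $1 + \beta_g(\text{composite} - 2) + \varepsilon$ with shallow negative
  slopes and Gaussian residuals (sd 0.1), five as pure noise around 1 —
  mirroring the observed split of significant and non-significant panels.
  Fold changes are clamped at 0.01 to stay positive; default slopes are
  chosen so clamping is vanishingly rare.
* **Promoters and motifs.** I.i.d. background sequence at configurable GC
  content; 50 random informative PFMs (length 8–12, dominant base weight
  at least 0.8 per column, pairwise-distinct consensus strings). Each
  "active" TF's exact consensus is planted, on a random strand and
  non-overlapping, in 80% of DE promoters and 10% of background
  promoters. The focal promoter carries one consensus site per focal TF
  (8 by default, 3 of them active). A truth record (JSON) logs every
  planted position, the active/silent/focal sets and the coupled slopes,
  so each stage is scored against construction, not re-derivation.
* **Expression floor.** Negative-control probes from a baseline normal
  (mean 6, sd 0.5 on the log-intensity-like scale); silent TFs drawn from
  the same distribution; expressed TFs shifted 4–8 baseline SDs up.

What it does **not** emulate: real promoter sequence composition
(repeats, CpG islands, GC heterogeneity), correlated probes, array
normalization artifacts, or any time-course structure beyond the four
group means. Tests passing on this generator therefore validate the
*inference machinery* — calibration, recovery, determinism — not
performance on genomic sequence.

# Validation problem sizes and scenario choices

The suite's statistical checks run at sizes chosen to make their
assertions sharp while staying desk-scale:

* Exact-oracle agreement uses a 10-gene universe with 4 DE genes (210
  subsets) and 50,000 resamples.
* Type-I calibration uses a null scenario (equal plant rates) with 200
  TFs over 5 seeds — 1,000 p-values — on a 500-gene universe; the
  observed $p < 0.05$ fraction must fall in the 99% binomial band around
  0.05. The empirical p is conservative by at most the discreteness of
  the count statistic, which the band accommodates.
* Planted-TF recovery runs the full default scenario with a single active
  TF across 100 seeds at 2,000 resamples.
* The unit-slope recovery scenario for the correlation screen uses a mild
  induction profile (group folds 1/1.2/1.12/1.05, sdlog 0.05) rather
  than the default 5-fold: with slope $-1$ the linear coupling model is
  only realizable while $1 - (c_{\max} - 2) - 3\sigma > 0$, i.e. the
  composite must stay below about 2.4; the mild profile satisfies the
  positivity constraint with room to spare while keeping the slope's
  noncentrality high. The default scenario instead pairs its strong
  induction with correspondingly shallow slopes.

# Known limitations

* **Power depends on motif specificity.** The planted signal is a fixed
  hit excess (about $|DE| \times (r_{de} - r_{bg})$), while the null SD of
  the total-hit statistic grows with the motif's background hit rate.
  Short, low-dominance motifs can accumulate several chance hits per
  kilobase at the default threshold, and for them a planted excess of
  ~35 hits sits only 2–3 null SDs out: real enrichment, but not at
  extreme p-values with a 2,000-resample floor. The recovery test in the
  acceptance suite measures exactly this, and its shortfall is confined
  to promiscuous motifs. On real data the practical mitigations are a
  stricter scan threshold, larger resample counts, or an
  information-content filter on the motif library — each a configuration
  choice, none a change to the test itself.
* **Exchangeable null.** Resampling genes uniformly assumes promoters are
  exchangeable under the null; real promoter sets differ in length, GC
  and repeat content, which would require a matched background.
* **Screens, not causes.** Both the driver triage and the target
  correlations are correlational screens. The target regressions in
  particular cannot distinguish direct repression from co-regulation —
  establishing causes takes mimic/inhibitor or knockout experiments.
* **Expression floor heuristic.** The $k$-SD rule with best-probe
  aggregation is a convention; probes are treated as exchangeable
  measurements of their gene.

# Reproducibility

Every random step flows from a single integer seed: the scenario
generator, the resampling null, and hence all written artifacts.
`run_pipeline()` writes a deterministic `report.json` (byte-identical
across reruns with one seed — asserted in the suite) plus a
`manifest.json` carrying the config snapshot, output digests and a
timestamp. Functions that consume randomness save and restore the
caller's RNG state.
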