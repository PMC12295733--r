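---
title: "Methods: eccDNA profiling, annotation, and clinical modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eccDNA profiling, annotation, and clinical modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccProfiler)
```

This vignette is the package's own account of what it computes and why:
the filtering and annotation rules, the feature scheme, the two modeling
stages, the synthetic-cohort generator that the test-suite exercises
everything on, and the places where the design was genuinely open and a
choice had to be made.

## 1. From circle calls to accepted circles

The pipeline starts from a candidate table as produced by split-read
circle callers: one row per candidate circle with its interval, the number
of supporting split reads and discordant read pairs, a caller confidence
score, and two coverage-derived statistics. All coordinates inside the
package are 0-based half-open (BED convention); readers that ingest
1-based sources convert at the boundary.

A candidate is accepted iff it clears **all five** criteria
(`apply_ecc_filters()`):

| id | criterion | default | direction |
|----|-----------|---------|-----------|
| C1 | split reads | 2 | ≥ |
| C2 | split + discordant support | 3 | ≥ |
| C3 | caller score | 50 | ≥ |
| C4 | breakpoint depth-increase ratio | 0.33 | strictly > |
| C5 | uncovered-base fraction inside the circle | 0.1 | strictly < |

The boundary semantics are fixed exactly as printed above: a candidate
with 2 split reads and score 50.0 passes C1/C3, one with a depth ratio of
exactly 0.33 fails C4. Two points needed a decision:

* **C4 combination rule.** Each circle has two breakpoints, hence two
  depth-increase ratios `(mean_in − mean_out)/mean_in` over flank-width
  windows (default 100 bp, clipped to [0, 1], defined 0 when the inside
  mean is 0). Whether an upstream rule of this kind uses the minimum, the
  mean, or either breakpoint is not recoverable from the criterion's usual
  statement; we default to the **minimum** (both junctions must clear
  0.33) as the conservative reading, with `breakpoint_rule = "mean"`
  available.
* **Missing coverage statistics.** Candidate tables do not always carry
  the C4/C5 columns. The default mode is *permissive* — the affected
  criterion is skipped with a warning — because rejecting a call for a
  missing diagnostic column conflates data quality with call quality;
  `missing_stats = "strict"` rejects instead. When a per-base depth array
  is available, `compute_coverage_stats()` reconstructs both statistics.

The filter returns an audit (per-candidate verdict and failed criterion
ids) rather than silently dropping rows; kept + rejected always equals the
input, the kept order is the input order, and tightening any threshold can
only shrink the kept set (both properties are under test).

## 2. Annotation catalog and overlap semantics

`build_annotation_catalog()` assembles 24 named interval sets: the gene
model's sub-features (gene, exon, intron, 5′/3′ UTR), derived tracks, the
regulatory tracks (enhancer, DHS, CpG island), CpG shores, and the
RepeatMasker-derived categories. Derived tracks are pure functions of
their inputs:

* **Gene flanks** are 2 kb windows adjacent to each gene span,
  strand-aware by default — "upstream" precedes the transcription start on
  the gene's own strand — because that is the standard biological reading
  of upstream/downstream; `strand_aware = FALSE` gives the coordinate-only
  interpretation. Flanks are clipped at chromosome bounds.
* **Intergenic** is the complement of the merged, strand-ignored gene
  spans within the genome, so overlapping genes cannot create negative
  gaps, and genic ∪ intergenic tiles every chromosome exactly (tested as
  an invariant).
* **Introns** are derived per gene as the gene span minus that gene's
  exons, rather than trusting an explicit intron track.
* **CpG shores** are strandless 2 kb windows on each side of every island.
* **DHS flanks** are off by default — whether open-chromatin regions
  should receive the same 2 kb treatment as CpG islands is ambiguous in
  common practice — with `dhs_flanks = TRUE` as the switch.
* **repeat_all** is the union of the seven RepeatMasker classes (SINE,
  LINE, LTR, DNA, simple repeat, low complexity, satellite); **Alu** and
  **MIR** are SINE families; **transposon** is defined as
  SINE ∪ LINE ∪ LTR ∪ DNA — the interspersed, transposon-derived classes —
  since "transposons" as a category has no single canonical definition.

`annotate_ecc()` marks a circle/category cell TRUE iff they share at least
1 bp — the bedtools-intersect default, with half-open abutment counting as
no overlap. The engine runs on GenomicRanges with the whole catalog pooled
into a single overlap query; the test-suite holds it to 100% agreement
with an independent all-pairs scan. Window densities (`window_density()`)
assign each circle to the 1 Mb window containing its **start** coordinate,
the simplest convention that counts every circle exactly once.

## 3. The 58-feature scheme

`quantify_sample()` maps a sample's overlap matrix to the default roster:

* 1 burden feature: circles per million mapped reads,
* 24 × per-million annotated count (`cpm_*`),
* 24 × annotated proportion (`prop_*`),
* 9 × raw annotated count (`count_*`) for gene, enhancer, DHS,
  repeat_all, SINE, LINE, LTR, Alu, MIR,

for 1 + 48 + 9 = 58 features. The roster is data
(`default_feature_roster()`), not code: any alternative enumeration with
the same columns can be swapped in, and the count of 58 is asserted only
for the default. All seven repeat classes are kept in the roster even
though some published feature sets use six: dropping one class is an
information-destroying choice we saw no principled basis for. Proportions
of a zero-circle sample are defined as 0 with a warning.

Group comparisons (`compare_groups()`) use the two-sided Wilcoxon
rank-sum test with tie correction and report **raw** p-values by default,
matching how per-feature panels of this kind are usually presented;
`adjust = "BH"` adds Benjamini–Hochberg adjustment.

## 4. Diagnostic harness

`run_diagnostic()` implements the model-comparison protocol: a stratified
2:1 train/test split, then for each of five families — random forest,
ridge-penalized logistic regression, Gaussian naive Bayes, RBF-kernel SVM,
KNN — a grid search scored by mean AUC over stratified ten-fold
cross-validation on the training set; the family with the best CV AUC
(ties toward the earlier family in the config order) is refit on the full
training set and evaluated once on the test set at the 0.5 probability
threshold (AUC is threshold-free). Default grids are deliberately small
(2–4 points per family, all in `default_grids()`), which keeps the full
harness near a second of compute at n ≈ 120 without hiding any grid in
code.

Standardization is per-family: the linear, margin, and neighbor models see
train-standardized features; the forest and naive Bayes see raw values —
the standard practice for these model classes. Determinism is end to end:
the seed fixes the split, the fold assignment, every stochastic fit, and
KNN's tie-breaking.

**Attribution** uses a Monte-Carlo permutation estimator of Shapley
values: for each explained instance and each sampled feature permutation,
a background row is drawn and features are switched from background to
instance values in permutation order; successive prediction differences
are the contributions, which average to Shapley values under the
interventional removal convention. For an additive model this converges to
the closed form `w_j (x_j − E[z_j])`, which the test-suite verifies.
Features are ranked by mean |value| and the top 10 reported. A cheaper
permutation-importance fallback (`permutation_importance()`) is provided
and labelled as such.

## 5. Survival stage

For each feature, `optimal_cutpoint()` runs the exhaustive log-rank scan:
candidate cutoffs are midpoints between consecutive sorted unique values
whose quantile lies within the 10th–90th percentile and whose high/low
sides both hold ≥ 3 samples; the cutoff maximizing the two-group log-rank
chi-square wins, ties toward the lower cutoff. Two honesty measures are
built in:

* the reported log-rank p at the selected cutoff is **flagged
  selection-biased** — maximizing over cutoffs inflates the statistic, so
  plain p < 0.05 counts from this screen overstate significance;
* an optional permutation correction (`permutation_B = 1000`) re-runs the
  full scan on feature-permuted data and reports the fraction of permuted
  maxima exceeding the observed one.

`univariate_cox()` fits the proportional-hazards model by partial
likelihood with Efron tie handling (the less-biased standard) and reports
HR, Wald 95% CI, and p; non-convergence and complete separation are
surfaced through a `converged` flag rather than a silent number. The
log-rank statistic itself is computed directly from the risk-set tables
(hypergeometric variance) so the cutpoint scan stays fast; the test-suite
pins it to `survival::survdiff` to 10 decimal places.

`prognostic_classifier()` reuses the diagnostic harness with the binary
DFS event as the label — the natural reading when a test-set AUC (rather
than a concordance index) is the reported metric. Samples lost to
follow-up (missing time/event) are excluded from survival stages only,
with a logged count. Because event counts are small, `run_pipeline()` caps
the fold count so that every fold's training part keeps at least two
samples of the minority class, and skips the classifier entirely (with a
message) when even two folds are infeasible.

## 6. The synthetic cohort generator

The generator (`simulate_cohort()`) exists so that every downstream claim
in the test-suite is grounded in data with known truth. Its defaults
encode the cohort structure the analysis targets:

* **Cohort**: 81 tumor, 33 normal samples; per-sample mapped reads uniform
  in 5–20 million; per-sample circle counts log-normally dispersed around
  300 (a desk-scale stand-in — real tissue cohorts reach orders of
  magnitude more calls, which would add nothing to the properties under
  test but minutes of runtime).
* **Lengths**: tumor circles from a two-component log-normal mixture with
  modes at 180 and 360 bp (weights 0.55/0.45, sdlog 0.2 — chosen so the
  two peaks are separable in a 10 bp histogram); normal circles from a
  single shorter mode at ~150 bp. Only the peak locations and the
  direction "tumor circles are longer on average" are treated as given;
  weights and variances are free parameters with these documented
  defaults.
* **Placement**: a category is drawn per circle from per-group weights
  (background mass placed uniformly), then the circle is anchored
  uniformly on a random interval of that category. Tumor weights are
  uplifted on enhancer/DHS/CpG and repeat categories relative to normal —
  the direction of the group differences the feature comparison is
  designed to detect. This is deliberately the simplest mechanism that
  plants proportion differences; it does not model clustering, hotspots,
  or copy-number structure.
* **Read support**: 90% of candidates are drawn to pass all five filters;
  each remaining candidate gets one uniformly chosen planted violation, so
  filter recall of the truth labels is exact by construction.
* **Survival**: event times are exponential proportional hazards on
  standardized planted features (defaults: log-HR 0.7 on the intron
  proportion, 0.5 on the repeat proportion — positive hazards on the
  categories reported as risk-linked in tissue studies), administrative
  censoring at 72 months, 10% random early censoring, and 10/81 lost to
  follow-up. The baseline hazard (0.0031/month) makes roughly 18% of
  followed patients experience an event, mirroring a 13-of-71 cohort. The
  exponential baseline (rather than Weibull) keeps closed-form sanity
  checks available.

Everything is a pure function of (config, seed): repeated runs write
byte-identical cohort trees, which the determinism tests assert file by
file.

**What passing tests do and do not show.** The generator produces clean,
exchangeable samples with independent per-circle placements and
exponential hazards. Real cohorts violate all of this: batch effects,
library-size-linked biases, spatial clustering of circles, subtype
structure, informative censoring. Green tests therefore certify the
*machinery* — formulas, conventions, determinism, calibration under the
null, power against planted effects — not the real-data effect sizes. In
particular, held-out AUCs on planted-effect synthetic cohorts mirror the
direction, not the magnitude, of any real cohort's performance.

## 7. Numerical choices and degenerate inputs

* Coverage ratios are clipped to [0, 1]; a zero inside-mean gives ratio 0
  (fails C4), an empty interval is an error.
* Constant features give Wilcoxon p = 1 (both groups identical) and are
  reported as "no admissible cutoff" by the cutpoint scan.
* Gaussian naive Bayes SDs are floored at 1e-9 to avoid NaN densities for
  within-class-constant features; KNN's k is capped at the training size.
* The log-rank variance term is skipped when the risk set has one subject;
  an all-censored comparison is an explicit error.
* Quantile bounds for cutpoint candidates use R's default type-7
  quantiles.
* Problem sizes in the test-suite were chosen to exercise each property at
  the smallest scale where it is statistically meaningful: oracle
  equivalence on 500–1,000 candidates, Cox recovery on 100 replicates of
  n = 400, harness calibration on 50 replicates of effect-free n = 120
  cohorts.

## 8. Known limitations

* The pipeline consumes circle-call tables; it does not realign reads or
  re-call circles, and read-level simulation is out of scope.
* Annotation is binary overlap (≥ 1 bp); fractional-overlap and
  nearest-feature statistics are not computed.
* The survival stage is univariate; multivariate Cox and time-dependent
  covariates are out of scope. Subtype-stratified analyses require an
  externally supplied subtype column.
* The naive per-feature survival screen is exploratory by construction;
  use the permutation-corrected p (or external validation) before treating
  any single feature as prognostic.
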