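# eccProfiler

Extrachromosomal circular DNA (eccDNA) — circular DNA molecules that exist
outside the chromosomes — is increasingly profiled in tumor tissue as a
candidate diagnostic and prognostic signal. A typical tissue workflow
enriches circular DNA, sequences it, calls candidate circles from split and
discordant reads (e.g. with Circle-Map), and then asks: which calls are
trustworthy, where do the circles come from in the genome, and do
genome-wide eccDNA summaries separate tumor from normal tissue or stratify
patient outcomes?

`eccProfiler` implements that downstream analysis as a tested, reusable R
pipeline for bioinformaticians working with circle-call tables:

* **Candidate filtering** — the five acceptance criteria applied to each
  candidate circle: split reads ≥ 2; split + discordant support ≥ 3; caller
  score ≥ 50; breakpoint depth-increase ratio > 0.33 at both junctions
  (ratio = (mean depth inside − mean depth outside)/mean depth inside over
  100 bp windows); fraction of uncovered bases inside the circle < 0.1.
  Both coverage statistics can be recomputed from per-base depth when the
  caller did not emit them.
* **Annotation** — every accepted circle is intersected (≥ 1 bp, BED
  half-open semantics) with 24 categories: gene / exon / intron / 5′ and 3′
  UTR, 2 kb gene flanks, the intergenic complement, enhancers, DHS, CpG
  islands and their 2 kb shores, the seven RepeatMasker classes and their
  union, Alu, MIR, and the transposon union (SINE ∪ LINE ∪ LTR ∪ DNA).
* **Quantification** — a 58-feature vector per sample: total circles per
  million mapped reads, plus a per-million count and a proportion for each
  category, plus raw counts for nine headline categories. Group differences
  are tested per feature with the two-sided Wilcoxon rank-sum test.
* **Diagnostic modeling** — a five-classifier harness (random forest,
  ridge logistic regression, Gaussian naive Bayes, RBF SVM, KNN) with a
  stratified 2:1 train/test split, ten-fold cross-validated grid search,
  held-out sensitivity/specificity/precision/F1/accuracy/AUC, and
  Monte-Carlo Shapley feature attribution.
* **Prognostic modeling** — per-feature optimal-cutoff binarization (the
  exhaustive log-rank scan over admissible cutpoints), Kaplan–Meier curves,
  log-rank tests, univariate Cox hazard ratios (Efron ties), and a
  disease-free-survival event classifier reusing the harness.
* **Synthetic cohorts** — a fully seeded generator that emulates the kind
  of cohort this analysis targets (81 tumor / 33 normal; bimodal tumor
  circle lengths peaking near 180 and 360 bp; placement enrichment on
  regulatory and repeat elements; ~18% DFS event rate with feature-linked
  hazards), so the whole pipeline is testable without access-controlled
  human data.

## Worked example

```r
library(eccProfiler)

cfg    <- simulation_config(seed = 42, n_tumor = 40, n_normal = 20,
                            ecc_per_sample = 200)
cohort <- simulate_cohort(cfg)
dir    <- file.path(tempdir(), "cohort")
out    <- file.path(tempdir(), "results")
write_cohort(cohort, dir)

res <- run_pipeline(dir, out, harness = harness_config(seed = 42, cv_folds = 5))

res$diagnostic$cv_table
#>                family               best_params    cv_auc
#> 1       random_forest mtry_rule=third,ntree=300 0.9666667
#> 2 logistic_regression               lambda=0.01 0.9555556
#> 3         naive_bayes                 laplace=0 0.9388889
#> 4                 svm                  cost=0.5 0.9444444
#> 5                 knn                      k=15 0.9333333

round(res$diagnostic$metrics, 3)
#> sensitivity specificity   precision          f1    accuracy         auc
#>       0.846       0.429       0.733       0.786       0.700       0.808
```

The cross-validation table says the random forest won the training-set
comparison (CV AUC 0.967) and was refit as the final model; the second
block is its held-out performance on the 20-sample test split (AUC 0.81 —
with only 6 test normals the specificity estimate is coarse). The planted
tumor/normal differences also surface exactly where the generator put
them, e.g. the per-feature Wilcoxon comparison:

```r
cmp <- res$comparison
head(cmp[order(cmp$p_value), c("feature", "median_normal", "median_tumor", "p_value")], 3)
#>           feature median_normal median_tumor      p_value
#> 35       prop_dhs    0.07927786   0.12500000 4.229810e-08
#> 34  prop_enhancer    0.06382708   0.09445117 2.586007e-07
#> 39 prop_repeat_all   0.58534647   0.64811183 3.872165e-06
```

i.e. the proportion of circles overlapping DHS regions is higher in tumor
samples (0.125 vs 0.079), and likewise for enhancer and repeat overlap.
`res$survival_screen` holds the per-feature optimal-cutoff hazard-ratio
table (note its log-rank p-values are flagged selection-biased — see the
methods vignette), and `out/` contains every table as TSV/JSON.

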