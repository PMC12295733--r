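# Shared fixtures, built once per test run.

tiny_config <- function(seed = 3L) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length_bp = 5e5,
                    n_tumor = 10, n_normal = 6, ecc_per_sample = 120)
}

# config with identical tumor/normal generating parameters and no planted
# hazards: the null cohort used by the calibration checks
null_config <- function(seed, n_tumor = 80, n_normal = 40,
                        ecc_per_sample = 300) {
  base <- simulation_config()
  simulation_config(
    seed = seed, n_tumor = n_tumor, n_normal = n_normal,
    ecc_per_sample = ecc_per_sample,
    length_mixture = list(tumor = base$length_mixture$normal,
                          normal = base$length_mixture$normal),
    category_weights = list(tumor = base$category_weights$normal,
                            normal = base$category_weights$normal),
    survival = modifyList(base$survival,
                          list(planted_loghr = c(prop_intron = 0))))
}

tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$cohort))
    tiny_cohort_env$cohort <- simulate_cohort(tiny_config())
  tiny_cohort_env$cohort
}

tiny_catalog <- function() {
  if (is.null(tiny_cohort_env$catalog)) {
    tr <- tiny_cohort()$tracks
    tiny_cohort_env$catalog <- build_annotation_catalog(
      tr$gene_model, tr$enhancer, tr$dhs, tr$cpg, tr$repeats, tr$layout)
  }
  tiny_cohort_env$catalog
}

# filter + annotate + quantify every sample of a cohort object
cohort_feature_matrix <- function(cohort, catalog = NULL,
                                  thresholds = filter_thresholds()) {
  if (is.null(catalog)) {
    tr <- cohort$tracks
    catalog <- build_annotation_catalog(tr$gene_model, tr$enhancer, tr$dhs,
                                        tr$cpg, tr$repeats, tr$layout)
  }
  vecs <- lapply(cohort$samples, function(s) {
    kept <- suppressWarnings(apply_ecc_filters(s$candidates, thresholds))$kept
    suppressWarnings(
      quantify_sample(annotate_ecc(kept, catalog), s$mapped_reads))
  })
  build_feature_matrix(vecs)
}

# independent all-pairs overlap oracle (>= 1 bp, half-open intervals)
brute_force_overlap <- function(ecc, catalog) {
  out <- matrix(FALSE, nrow(ecc), length(catalog),
                dimnames = list(NULL, names(catalog)))
  for (nm in names(catalog)) {
    iv <- catalog[[nm]]
    for (i in seq_len(nrow(ecc))) {
      same <- iv$chrom == ecc$chrom[i]
      out[i, nm] <- any(same & iv$start < ecc$end[i] & iv$end > ecc$start[i])
    }
  }
  out
}

# independent re-statement of the five acceptance predicates
brute_force_filter <- function(candidates, th = filter_thresholds()) {
  vapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    c1 <- r$split_reads >= th$min_split_reads
    c2 <- (r$split_reads + r$discordant_reads) >= th$min_total_support
    c3 <- r$score >= th$min_score
    c4 <- if (is.na(r$start_depth_ratio) || is.na(r$end_depth_ratio)) TRUE
    else min(r$start_depth_ratio, r$end_depth_ratio) > th$min_breakpoint_depth_ratio
    c5 <- if (is.na(r$uncovered_fraction)) TRUE
    else r$uncovered_fraction < th$max_uncovered_fraction
    c1 && c2 && c3 && c4 && c5
  }, logical(1))
}
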