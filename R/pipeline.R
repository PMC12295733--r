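#' Run the full eccDNA analysis pipeline on a cohort directory
#'
#' Executes the stages in order — filter the per-sample candidate tables,
#' annotate accepted circles against the track catalog, quantify every
#' sample into the feature roster, compare tumor versus normal per feature,
#' fit the diagnostic five-model harness, and run the survival stage
#' (per-feature optimal-cutpoint screening plus the DFS-event classifier).
#' All outputs plus the resolved configuration are written under `outdir`;
#' results are also returned in memory. The run is fully determined by
#' (inputs, configuration, seed).
#'
#' @param cohort_dir Directory in the layout written by [write_cohort()].
#' @param outdir Output directory (created).
#' @param thresholds [filter_thresholds()] for the candidate filter.
#' @param roster Feature roster (default [default_feature_roster()]).
#' @param harness [harness_config()] for the diagnostic model.
#' @param prognostic_harness [harness_config()] for the DFS-event model
#'   (defaults to `harness` with 5 CV folds, as event counts are small).
#' @param seed Global seed (overrides the seeds inside the harness configs).
#' @param stages Character subset of
#'   c("filter", "annotate", "quantify", "compare", "diagnose", "prognose");
#'   later stages require earlier ones.
#' @return List: `feature_matrix`, `labels`, `filter_summary`, `comparison`,
#'   `diagnostic`, `survival_screen`, `prognostic`.
#' @export
run_pipeline <- function(cohort_dir, outdir,
                         thresholds = filter_thresholds(),
                         roster = default_feature_roster(),
                         harness = harness_config(),
                         prognostic_harness = NULL,
                         seed = 1L,
                         stages = c("filter", "annotate", "quantify",
                                    "compare", "diagnose", "prognose")) {
  if (!file.exists(file.path(cohort_dir, "clinical.tsv")))
    stop("clinical table not found: ", file.path(cohort_dir, "clinical.tsv"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  harness$seed <- as.integer(seed)
  if (is.null(prognostic_harness)) {
    prognostic_harness <- harness
    prognostic_harness$cv_folds <- 5
  }
  prognostic_harness$seed <- as.integer(seed)
  cohort <- read_cohort(cohort_dir)
  tr <- cohort$tracks
  catalog <- build_annotation_catalog(tr$gene_model, tr$enhancer, tr$dhs,
                                      tr$cpg, tr$repeats, tr$layout)
  ids <- cohort$clinical$sample_id
  labels <- cohort$clinical$tissue_label
  kept <- list(); audits <- list()
  for (id in ids) {
    res <- suppressWarnings(
      apply_ecc_filters(cohort$samples[[id]]$candidates, thresholds))
    kept[[id]] <- res$kept
    audits[[id]] <- res$criterion_failures
  }
  filter_summary <- data.frame(
    sample_id = ids,
    n_input = vapply(ids, function(id)
      nrow(cohort$samples[[id]]$candidates), numeric(1)),
    n_kept = vapply(kept, nrow, numeric(1)), row.names = NULL,
    stringsAsFactors = FALSE)
  utils::write.table(filter_summary, file.path(outdir, "filter_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(filter_summary = filter_summary, labels = labels)
  if (!"quantify" %in% stages) return(invisible(out))
  vecs <- lapply(ids, function(id)
    suppressWarnings(quantify_sample(annotate_ecc(kept[[id]], catalog),
                                     cohort$clinical$mapped_reads[match(id, ids)],
                                     roster)))
  names(vecs) <- ids
  mat <- build_feature_matrix(vecs)
  write_feature_matrix(mat, file.path(outdir, "features.tsv"))
  out$feature_matrix <- mat
  if ("compare" %in% stages) {
    out$comparison <- compare_groups(mat, labels)
    utils::write.table(out$comparison, file.path(outdir, "wilcoxon.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("diagnose" %in% stages) {
    out$diagnostic <- run_diagnostic(mat, labels, harness)
    diag_json <- list(cv_table = out$diagnostic$cv_table,
                      best_family = out$diagnostic$best_family,
                      metrics = as.list(out$diagnostic$metrics),
                      attribution = out$diagnostic$attribution$ranking)
    jsonlite::write_json(diag_json, file.path(outdir, "diagnostic_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("prognose" %in% stages) {
    tum <- labels == "tumor"
    tmat <- mat[tum, , drop = FALSE]
    time <- cohort$clinical$dfs_time[tum]
    event <- cohort$clinical$dfs_event[tum]
    out$survival_screen <- suppressMessages(
      screen_survival_features(tmat, time, event))
    utils::write.table(out$survival_screen, file.path(outdir, "cox_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # the event class is small: cap the folds so every fold's training part
    # keeps >= 2 samples of it, and skip the classifier when infeasible
    minority <- min(sum(event == 1, na.rm = TRUE),
                    sum(event == 0, na.rm = TRUE))
    m_train <- round(minority * prognostic_harness$split_ratio)
    if (m_train >= 4) {
      prognostic_harness$cv_folds <-
        min(prognostic_harness$cv_folds, floor(m_train / 2))
      out$prognostic <- suppressMessages(
        prognostic_classifier(tmat, event, prognostic_harness))
      jsonlite::write_json(
        list(cv_table = out$prognostic$cv_table,
             best_family = out$prognostic$best_family,
             metrics = as.list(out$prognostic$metrics)),
        file.path(outdir, "prognostic_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      message("too few DFS events for the prognostic classifier; stage skipped")
    }
  }
  resolved <- list(seed = as.integer(seed), thresholds = unclass(thresholds),
                   harness = unclass(harness),
                   prognostic_harness = unclass(prognostic_harness),
                   stages = stages)
  jsonlite::write_json(resolved, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
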