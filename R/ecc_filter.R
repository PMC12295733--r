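#' Candidate-acceptance thresholds
#'
#' The five acceptance criteria applied to circle candidates:
#' C1 split reads >= `min_split_reads`; C2 split + discordant >=
#' `min_total_support`; C3 caller score >= `min_score`; C4 breakpoint depth
#' ratio (min of the two breakpoints by default) strictly greater than
#' `min_breakpoint_depth_ratio`; C5 uncovered-base fraction strictly less
#' than `max_uncovered_fraction`.
#'
#' @param min_split_reads Minimum supporting split reads (default 2).
#' @param min_total_support Minimum split + discordant support (default 3).
#' @param min_score Minimum caller score (default 50).
#' @param min_breakpoint_depth_ratio Strict lower bound on the breakpoint
#'   depth-increase ratio (default 0.33).
#' @param max_uncovered_fraction Strict upper bound on the fraction of
#'   zero-depth bases inside the circle (default 0.1).
#' @param breakpoint_rule How the two per-breakpoint ratios are combined for
#'   C4: "min" (both breakpoints must clear the bound) or "mean".
#' @param missing_stats Handling of candidates lacking the C4/C5 statistics:
#'   "permissive" skips the criterion with a warning, "strict" rejects.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_split_reads = 2, min_total_support = 3,
                              min_score = 50, min_breakpoint_depth_ratio = 0.33,
                              max_uncovered_fraction = 0.1,
                              breakpoint_rule = c("min", "mean"),
                              missing_stats = c("permissive", "strict")) {
  breakpoint_rule <- match.arg(breakpoint_rule)
  missing_stats <- match.arg(missing_stats)
  stopifnot(min_split_reads >= 0, min_total_support >= 0, min_score >= 0,
            min_breakpoint_depth_ratio >= 0, min_breakpoint_depth_ratio <= 1,
            max_uncovered_fraction >= 0, max_uncovered_fraction <= 1)
  structure(list(min_split_reads = min_split_reads,
                 min_total_support = min_total_support,
                 min_score = min_score,
                 min_breakpoint_depth_ratio = min_breakpoint_depth_ratio,
                 max_uncovered_fraction = max_uncovered_fraction,
                 breakpoint_rule = breakpoint_rule,
                 missing_stats = missing_stats),
            class = "filter_thresholds")
}

#' Coverage-derived breakpoint and continuity statistics
#'
#' Recomputes the two coverage statistics used by criteria C4/C5 from a
#' per-base depth array when the caller did not emit them. The array covers
#' `[start - flank, end + flank)` clipped at the chromosome bounds; the
#' depth-increase ratio at a breakpoint is `(mean_in - mean_out) / mean_in`
#' over flank-width windows just inside and outside the junction, clipped to
#' `[0, 1]` and defined as 0 when the inside mean is 0. The uncovered
#' fraction is the share of zero-depth bases within `[start, end)`.
#'
#' @param coverage Non-negative per-base depth vector over the padded window.
#' @param interval_start,interval_end Circle coordinates (0-based half-open).
#' @param flank_bp Flank/window width in bp (default 100).
#' @param window_start Genomic coordinate of `coverage[1]`; defaults to
#'   `interval_start - flank_bp` (use the clipped value near chromosome ends).
#' @return List with `start_depth_ratio`, `end_depth_ratio`,
#'   `uncovered_fraction`.
#' @export
compute_coverage_stats <- function(coverage, interval_start, interval_end,
                                   flank_bp = 100,
                                   window_start = interval_start - flank_bp) {
  stopifnot(flank_bp >= 1, interval_end > interval_start)
  if (any(coverage < 0)) stop("negative depth in coverage array")
  len <- interval_end - interval_start
  # index of interval_start within the array (1-based)
  i0 <- interval_start - window_start + 1
  i1 <- i0 + len - 1
  if (i0 < 1 || i1 > length(coverage))
    stop("coverage array shorter than the candidate interval")
  inside <- coverage[i0:i1]
  ratio_at <- function(in_idx, out_idx) {
    in_idx <- in_idx[in_idx >= 1 & in_idx <= length(coverage)]
    out_idx <- out_idx[out_idx >= 1 & out_idx <= length(coverage)]
    mean_in <- if (length(in_idx)) mean(coverage[in_idx]) else 0
    mean_out <- if (length(out_idx)) mean(coverage[out_idx]) else 0
    if (mean_in == 0) return(0)
    min(max((mean_in - mean_out) / mean_in, 0), 1)
  }
  w <- min(flank_bp, len)
  start_ratio <- ratio_at(i0:(i0 + w - 1), (i0 - flank_bp):(i0 - 1))
  end_ratio <- ratio_at((i1 - w + 1):i1, (i1 + 1):(i1 + flank_bp))
  list(start_depth_ratio = start_ratio,
       end_depth_ratio = end_ratio,
       uncovered_fraction = sum(inside == 0) / len)
}

#' Apply the five candidate-acceptance criteria
#'
#' Evaluates every candidate against the thresholds and returns the kept
#' subset (input order preserved) together with a per-candidate audit: the
#' verdict, the identifiers of failed criteria, and summary counts per
#' criterion. Inequality directions follow the published rule set: `>=` for
#' the three support/score criteria, strict `>` for the breakpoint depth
#' ratio, strict `<` for the uncovered fraction.
#'
#' @param candidates Candidate data.frame as from [read_candidate_table()].
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `kept` (data.frame), `audit` (data.frame: verdict,
#'   failed — comma-separated criterion ids), and `criterion_failures`
#'   (named counts C1..C5).
#' @export
apply_ecc_filters <- function(candidates, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(candidates)
  if (n == 0L) {
    return(list(kept = candidates,
                audit = data.frame(verdict = logical(0), failed = character(0)),
                criterion_failures = stats::setNames(integer(5),
                                                     paste0("C", 1:5))))
  }
  th <- thresholds
  c1 <- candidates$split_reads >= th$min_split_reads
  c2 <- (candidates$split_reads + candidates$discordant_reads) >=
    th$min_total_support
  c3 <- candidates$score >= th$min_score
  bp <- switch(th$breakpoint_rule,
               min = pmin(candidates$start_depth_ratio,
                          candidates$end_depth_ratio),
               mean = (candidates$start_depth_ratio +
                         candidates$end_depth_ratio) / 2)
  c4 <- bp > th$min_breakpoint_depth_ratio
  c5 <- candidates$uncovered_fraction < th$max_uncovered_fraction
  n_missing <- sum(is.na(c4)) + sum(is.na(c5))
  if (th$missing_stats == "permissive") {
    if (n_missing > 0)
      warning(sprintf("%d candidates lack coverage statistics; C4/C5 skipped for them",
                      sum(is.na(c4) | is.na(c5))))
    c4[is.na(c4)] <- TRUE
    c5[is.na(c5)] <- TRUE
  } else {
    c4[is.na(c4)] <- FALSE
    c5[is.na(c5)] <- FALSE
  }
  crit <- cbind(C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5)
  verdict <- rowSums(crit) == 5L
  failed <- apply(crit, 1, function(r) paste(colnames(crit)[!r], collapse = ","))
  kept <- candidates[verdict, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       audit = data.frame(verdict = verdict, failed = failed,
                          stringsAsFactors = FALSE),
       criterion_failures = colSums(!crit))
}
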