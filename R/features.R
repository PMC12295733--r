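#' The default 58-feature roster
#'
#' One burden feature (total circles per million mapped reads), a
#' per-million count and a proportion for each of the 24 annotation
#' categories, and a raw annotated-circle count for nine headline categories
#' (gene, enhancer, dhs, repeat_all, sine, line, ltr, alu, mir):
#' 1 + 48 + 9 = 58 features. The roster is data, not code: supply an
#' alternative data.frame with the same columns to change the scheme; the
#' count of 58 is enforced only for this default.
#'
#' @return data.frame with columns `name`, `kind` (one of total_per_million,
#'   count_per_million, proportion, raw_count), `category` (an annotation
#'   category, or NA for the total).
#' @export
default_feature_roster <- function() {
  cats <- annotation_categories()
  raw_cats <- c("gene", "enhancer", "dhs", "repeat_all", "sine", "line",
                "ltr", "alu", "mir")
  roster <- rbind(
    data.frame(name = "ecc_per_million", kind = "total_per_million",
               category = NA_character_, stringsAsFactors = FALSE),
    data.frame(name = paste0("cpm_", cats), kind = "count_per_million",
               category = cats, stringsAsFactors = FALSE),
    data.frame(name = paste0("prop_", cats), kind = "proportion",
               category = cats, stringsAsFactors = FALSE),
    data.frame(name = paste0("count_", raw_cats), kind = "raw_count",
               category = raw_cats, stringsAsFactors = FALSE))
  stopifnot(nrow(roster) == 58L, !anyDuplicated(roster$name))
  roster
}

validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster),
            all(c("name", "kind", "category") %in% names(roster)),
            !anyDuplicated(roster$name),
            all(roster$kind %in% c("total_per_million", "count_per_million",
                                   "proportion", "raw_count")))
  bad <- roster$kind != "total_per_million" &
    !roster$category %in% annotation_categories()
  if (any(bad))
    stop("roster references unknown categories: ",
         paste(unique(roster$category[bad]), collapse = ", "))
  roster
}

#' Quantify one sample into its feature vector
#'
#' Per-million features scale annotated-circle counts by
#' `1e6 / mapped_reads`; proportions divide by the number of accepted
#' circles (defined as 0 for a circle-free sample, with a warning).
#'
#' @param overlap Logical overlap matrix from [annotate_ecc()].
#' @param mapped_reads Mapped sequencing reads for the sample (> 0).
#' @param roster Feature roster (default [default_feature_roster()]).
#' @return Named numeric vector, one value per roster feature.
#' @export
quantify_sample <- function(overlap, mapped_reads,
                            roster = default_feature_roster()) {
  if (mapped_reads <= 0) stop("mapped_reads must be positive")
  roster <- validate_roster(roster)
  n_ecc <- nrow(overlap)
  if (n_ecc == 0L) warning("sample has zero accepted circles; proportions set to 0")
  n_cat <- colSums(overlap)
  val <- numeric(nrow(roster))
  for (i in seq_len(nrow(roster))) {
    kind <- roster$kind[i]
    val[i] <- switch(kind,
      total_per_million = n_ecc * 1e6 / mapped_reads,
      count_per_million = n_cat[[roster$category[i]]] * 1e6 / mapped_reads,
      proportion = if (n_ecc == 0L) 0 else n_cat[[roster$category[i]]] / n_ecc,
      raw_count = n_cat[[roster$category[i]]])
  }
  names(val) <- roster$name
  val
}

#' Stack per-sample feature vectors into a matrix
#'
#' @param vectors Named list of feature vectors (names = sample ids).
#' @return Numeric matrix samples x features.
#' @export
build_feature_matrix <- function(vectors) {
  stopifnot(length(vectors) > 0)
  m <- do.call(rbind, vectors)
  rownames(m) <- names(vectors)
  m
}

#' Tumor-versus-normal per-feature comparison
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) per feature, with group medians. Raw p-values are reported by
#' default, matching the convention of presenting unadjusted per-feature
#' tests; set `adjust = "BH"` for Benjamini-Hochberg adjustment.
#'
#' @param mat Feature matrix (samples x features).
#' @param labels Factor/character of group labels per sample (2 groups).
#' @param adjust "none" (default) or "BH".
#' @return data.frame feature, median per group, p_value (and p_adjusted
#'   when requested).
#' @export
compare_groups <- function(mat, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("compare_groups needs exactly 2 groups")
  a <- mat[labels == groups[1], , drop = FALSE]
  b <- mat[labels == groups[2], , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  p <- vapply(seq_len(ncol(mat)), function(j) {
    suppressWarnings(
      stats::wilcox.test(a[, j], b[, j], exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant feature across both groups
  out <- data.frame(feature = colnames(mat),
                    median_a = apply(a, 2, stats::median),
                    median_b = apply(b, 2, stats::median),
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("median_", groups)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(p, method = "BH")
  out
}

#' Per-group circle-length summary
#'
#' Arithmetic mean length, a fixed-width histogram (for inspecting the
#' bimodal small-circle peaks), and the two-group rank-sum p-value.
#'
#' @param ecc_a,ecc_b Interval data.frames for the two groups.
#' @param bin_bp Histogram bin width in bp (default 10).
#' @param max_bp Histogram upper bound (default 2000; longer circles fall in
#'   the last bin).
#' @return List with `mean_a`, `mean_b`, `p_value`, and `histogram`
#'   (data.frame: bin_start, count_a, count_b).
#' @export
length_summary <- function(ecc_a, ecc_b, bin_bp = 10, max_bp = 2000) {
  la <- ecc_a$end - ecc_a$start
  lb <- ecc_b$end - ecc_b$start
  if (length(la) == 0L || length(lb) == 0L) stop("both groups must be non-empty")
  breaks <- seq(0, max_bp, by = bin_bp)
  binify <- function(x) tabulate(pmin(x %/% bin_bp + 1, length(breaks)),
                                 nbins = length(breaks))
  p <- if (length(la) == length(lb) && all(sort(la) == sort(lb))) 1 else
    suppressWarnings(stats::wilcox.test(la, lb, exact = FALSE)$p.value)
  list(mean_a = mean(la), mean_b = mean(lb), p_value = p,
       histogram = data.frame(bin_start = breaks, count_a = binify(la),
                              count_b = binify(lb)))
}

#' Histogram modes of a length distribution
#'
#' Convenience for locating the dominant peaks: bins lengths at `bin_bp`,
#' lightly smooths with a 3-bin moving average, and returns the centers of
#' the `k` highest local maxima separated by at least `min_separation_bp`.
#'
#' @param lengths Numeric circle lengths (bp).
#' @param k Number of modes to return.
#' @param bin_bp Bin width (default 10).
#' @param min_separation_bp Minimum distance between reported modes.
#' @return Numeric vector of up to `k` mode locations (bp), ordered by
#'   prominence.
#' @export
length_modes <- function(lengths, k = 2, bin_bp = 10, min_separation_bp = 80) {
  h <- tabulate(floor(lengths / bin_bp) + 1)
  sm <- stats::filter(h, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  centers <- (seq_along(h) - 0.5) * bin_bp
  ord <- order(sm, decreasing = TRUE)
  modes <- numeric(0)
  for (i in ord) {
    if (length(modes) >= k) break
    if (all(abs(centers[i] - modes) >= min_separation_bp))
      modes <- c(modes, centers[i])
  }
  modes
}
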