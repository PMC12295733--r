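#' Read a chrom.sizes-style genome layout
#'
#' Parses a two-column whitespace-delimited table of chromosome names and
#' lengths into a `genome_layout` object. Declared chromosome order is
#' preserved and used for all downstream per-chromosome output.
#'
#' @param path Path to a chrom.sizes-format text file (name, length in bp).
#' @return A `genome_layout`: list with `chrom_names` (character) and
#'   `chrom_lengths` (named integer vector, bp).
#' @export
read_genome_layout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  names <- character(length(fields))
  lens <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop(sprintf("line %d: expected two columns (name, length)", i))
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len) || len != floor(len))
      stop(sprintf("line %d: non-integer chromosome length '%s'", i, f[2]))
    if (len <= 0)
      stop(sprintf("line %d: non-positive chromosome length %s", i, f[2]))
    names[i] <- f[1]
    lens[i] <- len
  }
  if (anyDuplicated(names))
    stop(sprintf("line %d: duplicate chromosome name '%s'",
                 which(duplicated(names))[1], names[duplicated(names)][1]))
  genome_layout(names, lens)
}

#' Construct a genome layout from vectors
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Positive integer lengths (bp), one per chromosome.
#' @return A `genome_layout` object.
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            !anyDuplicated(chrom_names), all(chrom_lengths > 0))
  lens <- as.numeric(chrom_lengths)
  names(lens) <- chrom_names
  structure(list(chrom_names = as.character(chrom_names), chrom_lengths = lens),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.0f bp total\n",
              length(x$chrom_names), sum(x$chrom_lengths)))
  invisible(x)
}

#' Write a genome layout as chrom.sizes text
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @export
write_genome_layout <- function(layout, path) {
  writeLines(sprintf("%s\t%.0f", layout$chrom_names, layout$chrom_lengths), path)
  invisible(path)
}

# Validate interval data.frame (chrom/start/end[/name/strand]) against a
# layout; all coordinates 0-based half-open. `where` labels error messages.
validate_intervals <- function(df, layout, where = "intervals") {
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("%s: line %d: end (%.0f) <= start (%.0f)", where, bad[1],
                 df$end[bad[1]], df$start[bad[1]]))
  bad <- which(df$start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: negative start", where, bad[1]))
  if (!is.null(layout)) {
    unknown <- which(!(df$chrom %in% layout$chrom_names))
    if (length(unknown))
      stop(sprintf("%s: line %d: unknown chromosome '%s'", where, unknown[1],
                   df$chrom[unknown[1]]))
    over <- which(df$end > layout$chrom_lengths[df$chrom])
    if (length(over))
      stop(sprintf("%s: line %d: interval end %.0f exceeds length of %s",
                   where, over[1], df$end[over[1]], df$chrom[over[1]]))
  }
  invisible(df)
}

#' Read a BED3/BED6 interval track
#'
#' Coordinates are kept in the BED convention used throughout the package:
#' 0-based half-open. `browser`/`track` header lines and comments are skipped.
#' Records are validated against `layout`; a malformed record aborts with its
#' line number rather than being dropped silently.
#'
#' @param path Path to a BED3/BED6 file.
#' @param layout A `genome_layout`, or NULL to skip bounds checking.
#' @return A data.frame with columns chrom, start, end, name, strand
#'   (strand one of "+", "-", "*").
#' @export
read_interval_track <- function(path, layout = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(browser|track|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    name = character(n), strand = character(n),
                    stringsAsFactors = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d: fewer than 3 BED columns", path, lineno[i]))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s: line %d: non-numeric coordinates", path, lineno[i]))
    out$chrom[i] <- f[1]; out$start[i] <- s; out$end[i] <- e
    out$name[i] <- if (length(f) >= 4L) f[4] else "."
    st <- if (length(f) >= 6L) f[6] else "*"
    # tolerate the unicode minus that shows up in hand-edited tracks
    if (st == "−") st <- "-"
    if (!st %in% c("+", "-", "*", "."))
      stop(sprintf("%s: line %d: bad strand '%s'", path, lineno[i], st))
    out$strand[i] <- if (st == ".") "*" else st
  }
  validate_intervals(out, layout, where = path)
  out
}

#' Write intervals as BED
#' @param df data.frame with chrom/start/end and optional name/strand.
#' @param path Output path.
#' @export
write_interval_track <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "*"] <- "."
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s",
                     df$chrom, df$start, df$end, name, strand), path)
  invisible(path)
}

#' Default Circle-Map Realign column mapping
#'
#' Positions of the fields in the documented 11-column Realign output:
#' chrom, start, end, discordant reads, split reads, circle score,
#' mean coverage, coverage SD, coverage increase at start, coverage increase
#' at end, coverage continuity. Override individual entries (or set one to
#' NA to mark the column absent) for other tool versions.
#'
#' @return Named integer vector of 1-based column positions.
#' @export
circlemap_column_map <- function() {
  c(chrom = 1L, start = 2L, end = 3L, discordant_reads = 4L, split_reads = 5L,
    score = 6L, mean_coverage = 7L, coverage_sd = 8L,
    start_depth_ratio = 9L, end_depth_ratio = 10L, uncovered_fraction = 11L)
}

#' Read a Circle-Map-style eccDNA candidate table
#'
#' Accepts headered or headerless TSV with columns in the Realign output
#' order (see [circlemap_column_map()]); a custom `column_map` overrides
#' positions when a different tool version reorders columns. The two
#' coverage-increase columns populate the per-breakpoint depth ratios and the
#' coverage-continuity column populates the uncovered-base fraction; '.' or a
#' missing column leaves the field NA.
#'
#' @param path Path to the TSV.
#' @param layout Optional `genome_layout` for bounds checking.
#' @param column_map Named positions as from [circlemap_column_map()].
#' @return A data.frame of candidates: chrom, start, end, discordant_reads,
#'   split_reads, score, mean_coverage, start_depth_ratio, end_depth_ratio,
#'   uncovered_fraction.
#' @export
read_candidate_table <- function(path, layout = NULL,
                                 column_map = circlemap_column_map()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_candidates())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # drop a header row: first line whose start column is not numeric
  first_start <- suppressWarnings(as.numeric(fields[[1]][column_map[["start"]]]))
  offset <- 0L
  if (is.na(first_start)) { fields <- fields[-1]; offset <- 1L }
  n <- length(fields)
  if (n == 0L) return(empty_candidates())
  need <- max(column_map[c("chrom", "start", "end", "discordant_reads",
                           "split_reads", "score")], na.rm = TRUE)
  grab <- function(f, key) {
    pos <- column_map[[key]]
    if (is.na(pos) || pos > length(f)) return(NA_character_)
    v <- f[pos]
    if (v == "." || v == "") NA_character_ else v
  }
  out <- empty_candidates(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- i + offset
    if (length(f) < need)
      stop(sprintf("%s: line %d: too few columns (%d, need %d)",
                   path, ln, length(f), need))
    out$chrom[i] <- f[column_map[["chrom"]]]
    out$start[i] <- as.numeric(f[column_map[["start"]]])
    out$end[i] <- as.numeric(f[column_map[["end"]]])
    out$discordant_reads[i] <- as.numeric(grab(f, "discordant_reads"))
    out$split_reads[i] <- as.numeric(grab(f, "split_reads"))
    out$score[i] <- as.numeric(grab(f, "score"))
    out$mean_coverage[i] <- as.numeric(grab(f, "mean_coverage"))
    out$start_depth_ratio[i] <- as.numeric(grab(f, "start_depth_ratio"))
    out$end_depth_ratio[i] <- as.numeric(grab(f, "end_depth_ratio"))
    out$uncovered_fraction[i] <- as.numeric(grab(f, "uncovered_fraction"))
    if (!is.na(out$split_reads[i]) && out$split_reads[i] < 0)
      stop(sprintf("%s: line %d: negative split-read count", path, ln))
    if (!is.na(out$discordant_reads[i]) && out$discordant_reads[i] < 0)
      stop(sprintf("%s: line %d: negative discordant-read count", path, ln))
  }
  validate_intervals(out, layout, where = path)
  for (col in c("start_depth_ratio", "end_depth_ratio", "uncovered_fraction")) {
    bad <- which(!is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1))
    if (length(bad))
      stop(sprintf("%s: line %d: %s outside [0,1]", path, bad[1] + offset, col))
  }
  out
}

empty_candidates <- function(n = 0L) {
  data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
             discordant_reads = numeric(n), split_reads = numeric(n),
             score = numeric(n), mean_coverage = numeric(n),
             start_depth_ratio = numeric(n), end_depth_ratio = numeric(n),
             uncovered_fraction = numeric(n), stringsAsFactors = FALSE)
}

#' Write an eccDNA candidate table in the Realign column order
#' @param candidates Candidate data.frame as from [read_candidate_table()].
#' @param path Output path.
#' @export
write_candidate_table <- function(candidates, path) {
  fmt <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 15))
  mean_cov <- if ("mean_coverage" %in% names(candidates))
    candidates$mean_coverage else NA_real_
  lines <- paste(candidates$chrom,
                 sprintf("%.0f", candidates$start),
                 sprintf("%.0f", candidates$end),
                 fmt(candidates$discordant_reads), fmt(candidates$split_reads),
                 fmt(candidates$score), fmt(mean_cov), fmt(NA_real_),
                 fmt(candidates$start_depth_ratio),
                 fmt(candidates$end_depth_ratio),
                 fmt(candidates$uncovered_fraction), sep = "\t")
  header <- paste("chrom", "start", "end", "discordant_reads", "split_reads",
                  "score", "mean_coverage", "coverage_sd", "start_depth_ratio",
                  "end_depth_ratio", "uncovered_fraction", sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read an rmsk-style repeat table
#'
#' BED-like TSV with three extra columns: repName, repClass, repFamily —
#' the layout of a UCSC RepeatMasker track export reduced to
#' (chrom, start, end, repName, repClass, repFamily).
#'
#' @param path Path to the table (header optional).
#' @param layout Optional `genome_layout`.
#' @return data.frame chrom, start, end, rep_name, rep_class, rep_family.
#' @export
read_repeat_table <- function(path, layout = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "rep_name",
                                        "rep_class", "rep_family"))
  if (is.na(suppressWarnings(as.numeric(df$start[1])))) df <- df[-1, , drop = FALSE]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  rownames(df) <- NULL
  validate_intervals(df, layout, where = path)
  df
}

#' Write an rmsk-style repeat table
#' @param df Repeat data.frame (chrom, start, end, rep_name, rep_class,
#'   rep_family).
#' @param path Output path.
#' @export
write_repeat_table <- function(df, path) {
  writeLines(c(paste("chrom", "start", "end", "repName", "repClass",
                     "repFamily", sep = "\t"),
               sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s", df$chrom, df$start,
                       df$end, df$rep_name, df$rep_class, df$rep_family)),
             path)
  invisible(path)
}

#' Convert a full UCSC rmsk export to the six-column repeat layout
#'
#' The genoName/genoStart/genoEnd/repName/repClass/repFamily columns of the
#' 17-column rmsk table are at positions 6, 7, 8, 11, 12, 13.
#'
#' @param path Path to a full rmsk TSV (no header).
#' @return data.frame in the package's six-column repeat layout.
#' @export
convert_rmsk_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 13L) stop("rmsk table needs >= 13 columns; got ", ncol(raw))
  data.frame(chrom = raw[[6]], start = as.numeric(raw[[7]]),
             end = as.numeric(raw[[8]]), rep_name = raw[[11]],
             rep_class = raw[[12]], rep_family = raw[[13]],
             stringsAsFactors = FALSE)
}

#' Read a gene-model table
#'
#' Flattened sub-feature BED with a feature-type column:
#' chrom, start, end, gene_id, strand, feature with feature in
#' {gene, exon, utr5, utr3}. Intron coordinates are derived downstream, so
#' they need not be listed.
#'
#' @param path Path to the table (header optional).
#' @param layout Optional `genome_layout`.
#' @return data.frame chrom, start, end, gene_id, strand, feature.
#' @export
read_gene_model <- function(path, layout = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "strand", "feature"))
  if (is.na(suppressWarnings(as.numeric(df$start[1])))) df <- df[-1, , drop = FALSE]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  rownames(df) <- NULL
  ok <- df$feature %in% c("gene", "exon", "intron", "utr5", "utr3")
  if (!all(ok))
    stop(sprintf("%s: line %d: unknown feature type '%s'", path,
                 which(!ok)[1], df$feature[!ok][1]))
  validate_intervals(df, layout, where = path)
  df
}

#' Write a gene-model table
#' @param df Gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_model <- function(df, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s", df$chrom, df$start, df$end,
                     df$gene_id, df$strand, df$feature), path)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with header columns sample_id, tissue_label, dfs_time, dfs_event,
#' mapped_reads; '.' marks missing DFS fields (which must be present or
#' absent together).
#'
#' @param path Path to the clinical TSV.
#' @return data.frame with one row per sample; dfs_time in months.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".")
  need <- c("sample_id", "tissue_label", "dfs_time", "dfs_event", "mapped_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$tissue_label %in% c("tumor", "normal"))
  if (length(bad))
    stop(sprintf("%s: line %d: tissue_label '%s' not one of {tumor, normal}",
                 path, bad[1] + 1L, df$tissue_label[bad[1]]))
  if (any(is.na(df$dfs_time) != is.na(df$dfs_event)))
    stop("dfs_time and dfs_event must be present or missing together")
  if (any(!is.na(df$dfs_event) & !df$dfs_event %in% c(0, 1)))
    stop("dfs_event must be 0 or 1")
  if (any(is.na(df$mapped_reads) | df$mapped_reads <= 0))
    stop("mapped_reads must be positive for every sample")
  df[, need]
}

#' Write a clinical table
#' @param df Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical_table <- function(df, path) {
  fmt <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  writeLines(c("sample_id\ttissue_label\tdfs_time\tdfs_event\tmapped_reads",
               paste(df$sample_id, df$tissue_label, fmt(df$dfs_time),
                     fmt(df$dfs_event), fmt(df$mapped_reads), sep = "\t")),
             path)
  invisible(path)
}

#' Write / read a feature matrix as TSV
#'
#' Samples in rows, named features in columns; the first column is the sample
#' identifier. Values round-trip within printed precision (15 significant
#' digits).
#'
#' @param mat Numeric matrix with rownames = sample ids, colnames = features.
#' @param path Output path.
#' @export
write_feature_matrix <- function(mat, path) {
  header <- paste(c("sample_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix()` returns the numeric matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
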