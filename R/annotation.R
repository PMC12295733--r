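#' The 24 annotation categories
#'
#' Functional categories (gene structure, derived gene flanks, intergenic
#' complement, enhancers, DHS, CpG islands and their 2 kb shores) followed by
#' the RepeatMasker-derived categories (seven repeat classes, their union,
#' the Alu and MIR SINE families, and the transposon union of the four
#' interspersed transposon-derived classes).
#'
#' @return Character vector of the 24 category names, in roster order.
#' @export
annotation_categories <- function() {
  c("gene", "exon", "intron", "utr5", "utr3",
    "gene_upstream_2kb", "gene_downstream_2kb", "intergenic",
    "enhancer", "dhs", "cpg_island", "cpg_upstream_2kb", "cpg_downstream_2kb",
    "repeat_all", "sine", "line", "ltr", "dna_repeat", "simple_repeat",
    "low_complexity", "satellite", "alu", "mir", "transposon")
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

# GRanges -> 0-based half-open data.frame
as_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# union+sort of a 0-based interval frame
merge_intervals <- function(df) {
  as_intervals(GenomicRanges::reduce(as_granges(df)))
}

# complement of (merged) intervals within the layout
complement_intervals <- function(df, layout) {
  out <- vector("list", length(layout$chrom_names))
  merged <- merge_intervals(df)
  for (k in seq_along(layout$chrom_names)) {
    ch <- layout$chrom_names[k]
    L <- layout$chrom_lengths[[ch]]
    sub <- merged[merged$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    starts <- c(0, sub$end)
    ends <- c(sub$start, L)
    keep <- ends > starts
    out[[k]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Derive gene-flank, intergenic, and CpG-shore tracks
#'
#' Upstream/downstream tracks are `flank_bp` windows adjacent to each gene
#' span, strand-aware by default (upstream precedes the transcription start
#' on the gene's strand) and clipped at chromosome bounds. The intergenic
#' track is the complement of the merged (strand-ignored) gene spans within
#' the genome. CpG shores are strandless `flank_bp` windows on each side of
#' every island.
#'
#' @param gene_model Gene-model data.frame as from [read_gene_model()].
#' @param cpg Interval data.frame of CpG islands.
#' @param layout A `genome_layout`.
#' @param flank_bp Flank width in bp (default 2000).
#' @param strand_aware Use gene strand for upstream/downstream (default TRUE);
#'   when FALSE, upstream means lower coordinates for every gene.
#' @return List of interval data.frames: `gene_upstream`, `gene_downstream`,
#'   `intergenic`, `cpg_upstream`, `cpg_downstream`.
#' @export
derive_tracks <- function(gene_model, cpg, layout, flank_bp = 2000,
                          strand_aware = TRUE) {
  genes <- gene_model[gene_model$feature == "gene", , drop = FALSE]
  validate_intervals(genes, layout, where = "gene model")
  clip <- function(df) {
    df$start <- pmax(df$start, 0)
    df$end <- pmin(df$end, layout$chrom_lengths[df$chrom])
    df[df$end > df$start, , drop = FALSE]
  }
  minus <- strand_aware & genes$strand == "-"
  up <- data.frame(chrom = genes$chrom,
                   start = ifelse(minus, genes$end, genes$start - flank_bp),
                   end = ifelse(minus, genes$end + flank_bp, genes$start),
                   stringsAsFactors = FALSE)
  down <- data.frame(chrom = genes$chrom,
                     start = ifelse(minus, genes$start - flank_bp, genes$end),
                     end = ifelse(minus, genes$start, genes$end + flank_bp),
                     stringsAsFactors = FALSE)
  list(gene_upstream = clip(up),
       gene_downstream = clip(down),
       intergenic = complement_intervals(genes, layout),
       cpg_upstream = clip(data.frame(chrom = cpg$chrom,
                                      start = cpg$start - flank_bp,
                                      end = cpg$start)),
       cpg_downstream = clip(data.frame(chrom = cpg$chrom, start = cpg$end,
                                        end = cpg$end + flank_bp)))
}

# per-gene introns: gene span minus that gene's exons (UTRs sit inside exons)
derive_introns <- function(gene_model) {
  genes <- gene_model[gene_model$feature == "gene", , drop = FALSE]
  exons <- gene_model[gene_model$feature %in% c("exon", "utr5", "utr3"), ,
                      drop = FALSE]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex) == 0L) {
      out[[i]] <- g[, c("chrom", "start", "end")]
      next
    }
    ex <- merge_intervals(ex)
    starts <- c(g$start, ex$end)
    ends <- c(ex$start, g$end)
    keep <- ends > starts & starts >= g$start & ends <= g$end
    if (any(keep))
      out[[i]] <- data.frame(chrom = g$chrom, start = starts[keep],
                             end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0))
  else res
}

#' Build the annotation catalog
#'
#' Assembles the 24 named interval sets the quantification stage classifies
#' against: gene-structure categories from the gene model (introns derived
#' per gene), the derived flank and intergenic tracks, enhancer / DHS / CpG
#' tracks, and the RepeatMasker categories with `repeat_all` the union of
#' the seven classes, Alu and MIR taken from the SINE families, and
#' `transposon` the union of SINE, LINE, LTR and DNA-repeat classes.
#'
#' @param gene_model Gene-model data.frame ([read_gene_model()]).
#' @param enhancer,dhs,cpg Interval data.frames (BED-like).
#' @param repeats Repeat data.frame ([read_repeat_table()]).
#' @param layout A `genome_layout`.
#' @param flank_bp Flank width for derived tracks (default 2000).
#' @param dhs_flanks Also add `flank_bp` shores around DHS regions into the
#'   dhs category (default FALSE).
#' @param strand_aware Passed to [derive_tracks()].
#' @return An `annotation_catalog`: named list of interval data.frames, one
#'   per category, plus the layout as attribute.
#' @export
build_annotation_catalog <- function(gene_model, enhancer, dhs, cpg, repeats,
                                     layout, flank_bp = 2000,
                                     dhs_flanks = FALSE, strand_aware = TRUE) {
  derived <- derive_tracks(gene_model, cpg, layout, flank_bp, strand_aware)
  sub <- function(feat) {
    d <- gene_model[gene_model$feature == feat, c("chrom", "start", "end"),
                    drop = FALSE]
    rownames(d) <- NULL
    d
  }
  rep_class <- function(cl) {
    d <- repeats[repeats$rep_class %in% cl, c("chrom", "start", "end"),
                 drop = FALSE]
    rownames(d) <- NULL
    d
  }
  rep_family <- function(fam) {
    d <- repeats[repeats$rep_family %in% fam, c("chrom", "start", "end"),
                 drop = FALSE]
    rownames(d) <- NULL
    d
  }
  dhs_track <- dhs[, c("chrom", "start", "end"), drop = FALSE]
  if (dhs_flanks) {
    shores <- rbind(
      data.frame(chrom = dhs$chrom, start = pmax(dhs$start - flank_bp, 0),
                 end = dhs$start),
      data.frame(chrom = dhs$chrom, start = dhs$end,
                 end = pmin(dhs$end + flank_bp,
                            layout$chrom_lengths[dhs$chrom])))
    dhs_track <- rbind(dhs_track, shores[shores$end > shores$start, ])
  }
  classes <- list(sine = "SINE", line = "LINE", ltr = "LTR",
                  dna_repeat = "DNA", simple_repeat = "Simple_repeat",
                  low_complexity = "Low_complexity", satellite = "Satellite")
  cat <- c(
    list(gene = sub("gene"), exon = sub("exon"),
         intron = derive_introns(gene_model),
         utr5 = sub("utr5"), utr3 = sub("utr3"),
         gene_upstream_2kb = derived$gene_upstream,
         gene_downstream_2kb = derived$gene_downstream,
         intergenic = derived$intergenic,
         enhancer = enhancer[, c("chrom", "start", "end"), drop = FALSE],
         dhs = dhs_track,
         cpg_island = cpg[, c("chrom", "start", "end"), drop = FALSE],
         cpg_upstream_2kb = derived$cpg_upstream,
         cpg_downstream_2kb = derived$cpg_downstream,
         repeat_all = rep_class(unlist(classes))),
    lapply(classes, rep_class),
    list(alu = rep_family("Alu"), mir = rep_family("MIR"),
         transposon = rep_class(c("SINE", "LINE", "LTR", "DNA"))))
  cat <- cat[annotation_categories()]
  for (nm in names(cat)) rownames(cat[[nm]]) <- NULL
  # one pooled GRanges (category in mcols) so classification is a single
  # overlap query per sample instead of one per category
  pooled <- do.call(rbind, lapply(names(cat), function(nm) {
    d <- cat[[nm]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end, category = nm,
               stringsAsFactors = FALSE)
  }))
  gr_all <- as_granges(pooled)
  S4Vectors::mcols(gr_all)$category <- factor(pooled$category,
                                              levels = names(cat))
  structure(cat, layout = layout, granges_all = gr_all,
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x), "categories\n")
  for (nm in names(x)) cat(sprintf("  %-20s %6d intervals\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Classify eccDNA against every catalog category
#'
#' A cell is TRUE iff the circle interval overlaps at least `min_overlap_bp`
#' bases (default 1, the bedtools-intersect convention) with at least one
#' interval of the category; categories are non-exclusive. Implemented on
#' the GenomicRanges overlap engine; a brute-force all-pairs scan is kept as
#' an independent oracle in the test-suite.
#'
#' @param ecc Interval data.frame of accepted circles (0-based half-open).
#' @param catalog An `annotation_catalog`.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return Logical matrix, rows = circles in input order, columns = the 24
#'   categories.
#' @export
annotate_ecc <- function(ecc, catalog, min_overlap_bp = 1) {
  stopifnot(inherits(catalog, "annotation_catalog"), min_overlap_bp >= 1)
  n <- nrow(ecc)
  out <- matrix(FALSE, nrow = n, ncol = length(catalog),
                dimnames = list(NULL, names(catalog)))
  if (n == 0L) return(out)
  q <- as_granges(ecc)
  gr_all <- attr(catalog, "granges_all")
  if (!is.null(gr_all)) {
    hits <- GenomicRanges::findOverlaps(q, gr_all,
                                        minoverlap = min_overlap_bp,
                                        ignore.strand = TRUE)
    cat_hit <- S4Vectors::mcols(gr_all)$category[S4Vectors::subjectHits(hits)]
    out[cbind(S4Vectors::queryHits(hits), as.integer(cat_hit))] <- TRUE
  } else {
    for (nm in names(catalog)) {
      out[, nm] <- GenomicRanges::countOverlaps(
        q, as_granges(catalog[[nm]]), minoverlap = min_overlap_bp,
        ignore.strand = TRUE) > 0
    }
  }
  out
}

#' eccDNA density in fixed genomic windows
#'
#' Tiles every chromosome with `window_bp` windows and counts each circle in
#' the window containing its start coordinate, so each circle is counted
#' exactly once.
#'
#' @param ecc Interval data.frame of circles.
#' @param layout A `genome_layout`.
#' @param window_bp Window size in bp (default 1e6).
#' @return data.frame chrom, window_start, window_end, count.
#' @export
window_density <- function(ecc, layout, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive")
  out <- vector("list", length(layout$chrom_names))
  for (k in seq_along(layout$chrom_names)) {
    ch <- layout$chrom_names[k]
    L <- layout$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = window_bp)
    ends <- pmin(starts + window_bp, L)
    idx <- ecc$start[ecc$chrom == ch] %/% window_bp + 1
    counts <- tabulate(idx, nbins = length(starts))
    out[[k]] <- data.frame(chrom = ch, window_start = starts,
                           window_end = ends, count = counts,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fraction of circles on each chromosome
#'
#' @param ecc Interval data.frame of circles.
#' @param layout A `genome_layout` (fixes chromosome order; chromosomes with
#'   no circles report 0).
#' @return Named numeric vector summing to 1 (all zeros if `ecc` is empty).
#' @export
per_chromosome_proportions <- function(ecc, layout) {
  counts <- table(factor(ecc$chrom, levels = layout$chrom_names))
  p <- as.numeric(counts)
  names(p) <- layout$chrom_names
  if (sum(p) > 0) p <- p / sum(p)
  p
}
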