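test_that("derived gene flanks are strand-aware and clipped", {
  lay <- genome_layout("chrA", 1e6)
  gm <- data.frame(chrom = "chrA", start = c(5000, 500), end = c(8000, 900),
                   gene_id = c("g1", "g2"), strand = c("+", "+"),
                   feature = "gene", stringsAsFactors = FALSE)
  d <- derive_tracks(gm, data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)), lay)
  up <- d$gene_upstream[order(d$gene_upstream$start), ]
  expect_equal(up$start, c(0, 3000))
  expect_equal(up$end, c(500, 5000))   # g2 clipped at the chromosome start
  expect_equal(d$gene_downstream$start[1], 8000)
  expect_equal(d$gene_downstream$end[1], 10000)

  # minus-strand gene: upstream sits after the span
  gm$strand <- c("-", "-")
  d <- derive_tracks(gm, data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)), lay)
  expect_true(any(d$gene_upstream$start == 8000 & d$gene_upstream$end == 10000))
})

test_that("intergenic is the merged-gene complement", {
  lay <- genome_layout("chrA", 1000)
  gm <- data.frame(chrom = "chrA", start = c(100, 150), end = c(200, 300),
                   gene_id = c("g1", "g2"), strand = "+", feature = "gene",
                   stringsAsFactors = FALSE)
  d <- derive_tracks(gm, data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)), lay, flank_bp = 10)
  ig <- d$intergenic[order(d$intergenic$start), ]
  expect_equal(ig$start, c(0, 300))
  expect_equal(ig$end, c(100, 1000))
})

test_that("genic and intergenic partition every simulated genome", {
  for (seed in c(3, 11)) {
    co <- simulate_genome_and_tracks(tiny_config(seed))
    catalog <- build_annotation_catalog(co$gene_model, co$enhancer, co$dhs,
                                        co$cpg, co$repeats, co$layout)
    genic <- catalog$gene
    inter <- catalog$intergenic
    both <- rbind(genic[, c("chrom", "start", "end")],
                  inter[, c("chrom", "start", "end")])
    # union covers the genome
    covered <- sum(eccProfiler:::merge_intervals(both)$end -
                     eccProfiler:::merge_intervals(both)$start)
    expect_equal(covered, sum(co$layout$chrom_lengths))
    # and the two sets are disjoint
    ov <- annotate_ecc(inter, catalog)[, "gene"]
    expect_false(any(ov))
  }
})

test_that("single-bp overlap counts; half-open abutment does not", {
  lay <- genome_layout("chrA", 1e5)
  gm <- data.frame(chrom = "chrA", start = 19, end = 30, gene_id = "g1",
                   strand = "+", feature = "gene", stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  reps <- data.frame(chrom = "chrA", start = 50, end = 60, rep_name = "r1",
                     rep_class = "SINE", rep_family = "Alu",
                     stringsAsFactors = FALSE)
  catalog <- build_annotation_catalog(gm, empty, empty, empty, reps, lay)
  ecc <- data.frame(chrom = "chrA", start = c(10, 10, 40), end = c(20, 19, 50))
  ov <- annotate_ecc(ecc, catalog)
  expect_equal(unname(ov[, "gene"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(ov[, "sine"]), c(FALSE, FALSE, FALSE))  # [40,50) vs [50,60)
})

test_that("catalog invariants hold on simulated tracks", {
  catalog <- tiny_catalog()
  expect_setequal(names(catalog), annotation_categories())
  co <- tiny_cohort()
  ecc <- do.call(rbind, lapply(co$samples[1:6], function(s)
    s$candidates[, c("chrom", "start", "end")]))
  ov <- annotate_ecc(ecc, catalog)
  seven <- c("sine", "line", "ltr", "dna_repeat", "simple_repeat",
             "low_complexity", "satellite")
  expect_equal(ov[, "repeat_all"],
               apply(ov[, seven], 1, any))
  expect_equal(ov[, "transposon"],
               apply(ov[, c("sine", "line", "ltr", "dna_repeat")], 1, any))
  expect_true(all(!ov[, "alu"] | ov[, "sine"]))
  expect_true(all(!ov[, "mir"] | ov[, "sine"]))
  # genome partition: every circle hits genic or intergenic
  expect_true(all(ov[, "gene"] | ov[, "intergenic"]))
})

test_that("overlap engine agrees with the all-pairs oracle", {
  catalog <- tiny_catalog()
  co <- tiny_cohort()
  ecc <- do.call(rbind, lapply(co$samples[1:3], function(s)
    s$candidates[, c("chrom", "start", "end")]))
  rownames(ecc) <- NULL
  expect_identical(annotate_ecc(ecc, catalog), brute_force_overlap(ecc, catalog))
})

test_that("window density counts circles once, by start coordinate", {
  lay <- genome_layout(c("chrA", "chrB"), c(2.5e6, 1e6))
  ecc <- data.frame(chrom = "chrA", start = seq(0, 9e5, 1e5),
                    end = seq(0, 9e5, 1e5) + 500)
  wd <- window_density(ecc, lay)
  expect_equal(wd$count[wd$chrom == "chrA"], c(10, 0, 0))
  expect_equal(sum(wd$count), nrow(ecc))
  expect_equal(wd$window_end[3], 2.5e6)  # last window clipped
  expect_error(window_density(ecc, lay, window_bp = 0), "positive")

  p <- per_chromosome_proportions(ecc, lay)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p["chrB"]), 0)
})

test_that("uniform placement spreads evenly across equal chromosomes", {
  lay <- genome_layout(c("c1", "c2"), c(1e6, 1e6))
  set.seed(9)
  n <- 10000
  ecc <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    start = floor(runif(n, 0, 1e6 - 100)))
  ecc$end <- ecc$start + 100
  p <- per_chromosome_proportions(ecc, lay)
  expect_true(all(abs(p - 0.5) < 0.05))
})
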