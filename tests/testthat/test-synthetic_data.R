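test_that("simulation is fully deterministic: byte-identical cohort trees", {
  cfg <- tiny_config(seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # and a different seed changes the outputs
  write_cohort(simulate_cohort(tiny_config(seed = 9)), d2)
  expect_false(identical(readLines(file.path(d1, "samples", "T001.tsv")),
                         readLines(file.path(d2, "samples", "T001.tsv"))))
})

test_that("all tracks are non-degenerate and within the layout", {
  tr <- simulate_genome_and_tracks(tiny_config())
  expect_equal(sort(unique(tr$repeats$rep_class)),
               sort(c("SINE", "LINE", "LTR", "DNA", "Simple_repeat",
                      "Low_complexity", "Satellite")))
  expect_true(all(c("Alu", "MIR") %in%
                    tr$repeats$rep_family[tr$repeats$rep_class == "SINE"]))
  for (d in list(tr$enhancer, tr$dhs, tr$cpg, tr$repeats, tr$gene_model)) {
    expect_gt(nrow(d), 0)
    expect_true(all(d$start >= 0))
    expect_true(all(d$end <= tr$layout$chrom_lengths[d$chrom]))
    expect_true(all(d$end > d$start))
  }
  expect_error(simulate_genome_and_tracks(
    simulation_config(chrom_length_bp = 1e4)), "short")
})

test_that("candidates generated as failures are all rejected by the filter", {
  co <- tiny_cohort()
  for (s in co$samples) {
    res <- apply_ecc_filters(s$candidates)
    expect_identical(res$audit$verdict, s$truth_pass)
  }
})

test_that("tumor circles are longer than normal circles under the defaults", {
  tr <- simulate_genome_and_tracks(tiny_config())
  cfg <- tiny_config()
  wins <- 0
  for (r in 1:20) {
    st <- simulate_sample(tr, cfg, "tumor", seed = 3000 + r)
    sn <- simulate_sample(tr, cfg, "normal", seed = 4000 + r)
    mt <- mean(st$candidates$end - st$candidates$start)
    mn <- mean(sn$candidates$end - sn$candidates$start)
    if (mt > mn) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("a null config makes the groups statistically indistinguishable", {
  cfg <- null_config(seed = 17, n_tumor = 12, n_normal = 12,
                     ecc_per_sample = 150)
  co <- simulate_cohort(cfg)
  mat <- cohort_feature_matrix(co)
  res <- compare_groups(mat, co$clinical$tissue_label)
  # under the null, small p-values occur at roughly the nominal rate
  expect_lt(mean(res$p_value < 0.05), 0.25)
  expect_gt(min(res$p_value), 1e-5)
})

test_that("survival planting: zero horizon, null hazards, planted hazards", {
  m <- matrix(rnorm(200), 100, 2,
              dimnames = list(sprintf("s%03d", 1:100),
                              c("prop_intron", "prop_repeat_all")))
  cfg <- simulation_config()
  cfg$survival$horizon_months <- 0
  cfg$survival$lost_fraction <- 0
  sv <- simulate_survival(m, cfg, seed = 5)
  expect_true(all(sv$dfs_time == 0))
  expect_true(all(sv$dfs_event == 0))

  expect_error(simulate_survival(
    matrix(0, 4, 1, dimnames = list(letters[1:4], "other")),
    simulation_config(), seed = 1), "absent")

  # null hazards: Cox CI covers HR = 1 in most replicates
  cfg0 <- simulation_config()
  cfg0$survival$planted_loghr <- c(prop_intron = 0)
  cfg0$survival$lost_fraction <- 0
  cfg0$survival$baseline_hazard <- 0.01
  covered <- 0
  for (r in 1:50) {
    x <- matrix(rnorm(160), 80, 2,
                dimnames = list(sprintf("s%02d", 1:80),
                                c("prop_intron", "prop_repeat_all")))
    sv <- simulate_survival(x, cfg0, seed = 900 + r)
    cx <- univariate_cox(x[, 1], sv$dfs_time, sv$dfs_event)
    if (cx$ci_low <= 1 && cx$ci_high >= 1) covered <- covered + 1
  }
  expect_gte(covered, 45)

  # planted positive hazard raises the event rate in the top half
  cfgp <- simulation_config()
  cfgp$survival$planted_loghr <- c(prop_intron = 1.5)
  cfgp$survival$lost_fraction <- 0
  cfgp$survival$baseline_hazard <- 0.005
  x <- matrix(rnorm(400), 400, 1,
              dimnames = list(sprintf("s%03d", 1:400), "prop_intron"))
  sv <- simulate_survival(x, cfgp, seed = 31)
  hi <- x[, 1] > median(x[, 1])
  expect_gt(mean(sv$dfs_event[hi]), mean(sv$dfs_event[!hi]))
})

test_that("cohort clinical table mirrors the samples and planted outcomes", {
  co <- tiny_cohort()
  cl <- co$clinical
  expect_equal(nrow(cl), length(co$samples))
  expect_true(all(is.na(cl$dfs_time[cl$tissue_label == "normal"])))
  expect_true(all(cl$mapped_reads > 0))
  expect_equal(cl$mapped_reads,
               vapply(co$samples, `[[`, numeric(1), "mapped_reads"),
               ignore_attr = TRUE)
  # truth serialization carries the per-sample pass labels
  expect_identical(co$truth$pass[[1]], co$samples[[1]]$truth_pass)
})
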