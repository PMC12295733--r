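#' Simulation configuration for a synthetic eccDNA cohort
#'
#' Defaults emulate the profiled cohort: 81 tumor and 33 matched normal
#' samples; tumor circle lengths from a two-component log-normal mixture
#' with modes near 180 and 360 bp against a single shorter normal mode;
#' tumor placement probability uplifted on regulatory (enhancer, DHS, CpG)
#' and repeat categories; roughly 18% of followed tumor patients
#' experiencing a DFS event, with a planted positive log-hazard on the
#' intron and total-repeat proportions and about 12% of patients lost to
#' follow-up.
#'
#' @param seed Base seed; together with the config it fully determines every
#'   simulated output.
#' @param n_chroms,chrom_length_bp Toy genome size controls.
#' @param n_tumor,n_normal Cohort sizes (defaults 81 and 33).
#' @param ecc_per_sample Mean accepted-circle count per sample.
#' @param ecc_dispersion SD of the log-normal sample-to-sample burden factor.
#' @param length_mixture Per-group log-normal mixture parameters (lists with
#'   `meanlog`, `sdlog`, `weight`).
#' @param category_weights Per-group placement probabilities over the
#'   placement categories (must each sum to 1; "background" is uniform
#'   genome placement).
#' @param pass_fraction Fraction of generated candidates given read support
#'   that clears the acceptance criteria (default 0.9); the remainder are
#'   constructed to violate at least one criterion.
#' @param mapped_reads_range Integer range for per-sample mapped reads.
#' @param survival List: `baseline_hazard` (events/month),
#'   `planted_loghr` (named per-feature log-hazard ratios applied to
#'   standardized features), `horizon_months`, `censoring_fraction`
#'   (random early censoring), `lost_fraction` (missing DFS fields).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chroms = 2L,
    chrom_length_bp = 1e6,
    n_tumor = 81L,
    n_normal = 33L,
    ecc_per_sample = 300,
    ecc_dispersion = 0.35,
    length_mixture = list(
      tumor = list(meanlog = c(log(180) + 0.2^2, log(360) + 0.2^2),
                   sdlog = c(0.2, 0.2), weight = c(0.55, 0.45)),
      normal = list(meanlog = log(150) + 0.35^2, sdlog = 0.35, weight = 1)),
    category_weights = list(
      tumor = c(background = 0.15, gene = 0.28, enhancer = 0.06, dhs = 0.08,
                cpg_island = 0.06, sine = 0.09, line = 0.09, ltr = 0.06,
                dna_repeat = 0.05, simple_repeat = 0.04, low_complexity = 0.03,
                satellite = 0.01),
      normal = c(background = 0.30, gene = 0.30, enhancer = 0.03, dhs = 0.04,
                 cpg_island = 0.03, sine = 0.08, line = 0.08, ltr = 0.04,
                 dna_repeat = 0.04, simple_repeat = 0.03, low_complexity = 0.02,
                 satellite = 0.01)),
    pass_fraction = 0.9,
    mapped_reads_range = c(5e6, 2e7),
    survival = list(baseline_hazard = 0.0031,
                    planted_loghr = c(prop_intron = 0.7, prop_repeat_all = 0.5),
                    horizon_months = 72,
                    censoring_fraction = 0.1,
                    lost_fraction = 10 / 81)) {
  for (g in names(length_mixture)) {
    w <- length_mixture[[g]]$weight
    if (abs(sum(w) - 1) > 1e-9) stop("length mixture weights must sum to 1")
  }
  for (g in names(category_weights)) {
    if (abs(sum(category_weights[[g]]) - 1) > 1e-9)
      stop("category weights must sum to 1")
    if (any(category_weights[[g]] < 0)) stop("category weights must be >= 0")
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length_bp = chrom_length_bp, n_tumor = n_tumor,
                 n_normal = n_normal, ecc_per_sample = ecc_per_sample,
                 ecc_dispersion = ecc_dispersion,
                 length_mixture = length_mixture,
                 category_weights = category_weights,
                 pass_fraction = pass_fraction,
                 mapped_reads_range = mapped_reads_range,
                 survival = survival),
            class = "simulation_config")
}

# deterministic sub-seed stream, kept within 32-bit range
sub_seed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_intervals <- function(n, layout, min_len, max_len, prefix) {
  ch <- sample(layout$chrom_names, n, replace = TRUE,
               prob = layout$chrom_lengths / sum(layout$chrom_lengths))
  len <- round(stats::runif(n, min_len, max_len))
  start <- floor(stats::runif(n) * (layout$chrom_lengths[ch] - len))
  data.frame(chrom = ch, start = start, end = start + len,
             name = sprintf("%s%d", prefix, seq_len(n)),
             strand = "*", stringsAsFactors = FALSE)
}

#' Simulate the toy genome and annotation tracks
#'
#' Builds the genome layout and every track the annotation stage consumes:
#' a gene model with exons, UTRs and both strands; enhancer, DHS and
#' CpG-island BED tracks; and an rmsk-style repeat table containing all
#' seven repeat classes with Alu and MIR families inside SINE. Element
#' counts scale with genome size; every category is guaranteed non-empty.
#'
#' @param config A [simulation_config()].
#' @return List: `layout`, `gene_model`, `enhancer`, `dhs`, `cpg`, `repeats`.
#' @export
simulate_genome_and_tracks <- function(config = simulation_config()) {
  layout <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                          rep(config$chrom_length_bp, config$n_chroms))
  total <- sum(layout$chrom_lengths)
  if (config$chrom_length_bp < 1e5)
    stop("chromosomes shorter than 1e5 bp cannot hold the requested tracks")
  with_seed(sub_seed(config$seed, 1), {
    # genes: non-overlapping spans laid down chromosome by chromosome
    gm <- list()
    gid <- 0L
    for (ch in layout$chrom_names) {
      L <- layout$chrom_lengths[[ch]]
      pos <- 5000
      while (pos < L - 30000) {
        gid <- gid + 1L
        glen <- round(stats::runif(1, 4000, 20000))
        strand <- sample(c("+", "-"), 1)
        gstart <- pos
        gend <- gstart + glen
        n_exon <- sample(2:5, 1)
        # exon starts spread across the gene, fixed 300-800 bp exons
        estarts <- sort(round(stats::runif(n_exon, gstart, gend - 900)))
        elens <- round(stats::runif(n_exon, 300, 800))
        eends <- pmin(estarts + elens, gend)
        keep <- eends > estarts
        estarts <- estarts[keep]; eends <- eends[keep]
        # clip exon overlaps
        for (k in seq_along(estarts)[-1])
          estarts[k] <- max(estarts[k], eends[k - 1])
        keep <- eends > estarts
        estarts <- estarts[keep]; eends <- eends[keep]
        id <- sprintf("gene%04d", gid)
        rows <- data.frame(chrom = ch,
                           start = c(gstart, estarts),
                           end = c(gend, eends),
                           gene_id = id, strand = strand,
                           feature = c("gene", rep("exon", length(estarts))),
                           stringsAsFactors = FALSE)
        # UTRs: leading/trailing 150 bp of the first/last exon
        if (length(estarts) >= 1) {
          first <- if (strand == "+") 1 else length(estarts)
          last <- if (strand == "+") length(estarts) else 1
          u5 <- c(estarts[first], min(estarts[first] + 150, eends[first]))
          u3 <- c(max(eends[last] - 150, estarts[last]), eends[last])
          rows <- rbind(rows,
                        data.frame(chrom = ch, start = c(u5[1], u3[1]),
                                   end = c(u5[2], u3[2]), gene_id = id,
                                   strand = strand,
                                   feature = c("utr5", "utr3"),
                                   stringsAsFactors = FALSE))
        }
        gm[[length(gm) + 1L]] <- rows
        pos <- gend + round(stats::runif(1, 8000, 25000))
      }
    }
    gene_model <- do.call(rbind, gm)
    per_mb <- total / 1e6
    enhancer <- rand_intervals(max(20, round(40 * per_mb)), layout, 200, 1500, "enh")
    dhs <- rand_intervals(max(30, round(60 * per_mb)), layout, 150, 900, "dhs")
    cpg <- rand_intervals(max(15, round(30 * per_mb)), layout, 300, 2000, "cpg")
    rep_spec <- list(
      SINE = c(n = 120, lo = 100, hi = 350),
      LINE = c(n = 60, lo = 500, hi = 6000),
      LTR = c(n = 40, lo = 300, hi = 5000),
      DNA = c(n = 40, lo = 150, hi = 2500),
      Simple_repeat = c(n = 50, lo = 30, hi = 200),
      Low_complexity = c(n = 40, lo = 30, hi = 300),
      Satellite = c(n = 15, lo = 500, hi = 5000))
    reps <- list()
    for (cl in names(rep_spec)) {
      sp <- rep_spec[[cl]]
      n <- max(5, round(sp[["n"]] * per_mb))
      iv <- rand_intervals(n, layout, sp[["lo"]], sp[["hi"]], tolower(cl))
      fam <- if (cl == "SINE")
        sample(c("Alu", "MIR", "tRNA"), n, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
      else cl
      reps[[cl]] <- data.frame(chrom = iv$chrom, start = iv$start,
                               end = iv$end, rep_name = iv$name,
                               rep_class = cl, rep_family = fam,
                               stringsAsFactors = FALSE)
    }
    repeats <- do.call(rbind, reps)
    rownames(repeats) <- NULL
    # SINE families must both be represented for the alu/mir categories
    sine_rows <- which(repeats$rep_class == "SINE")
    repeats$rep_family[sine_rows[1]] <- "Alu"
    repeats$rep_family[sine_rows[2]] <- "MIR"
    list(layout = layout, gene_model = gene_model, enhancer = enhancer,
         dhs = dhs, cpg = cpg, repeats = repeats)
  })
}

# placement track lookup for a named placement category
placement_pool <- function(tracks, category) {
  switch(category,
    gene = tracks$gene_model[tracks$gene_model$feature == "gene", ],
    enhancer = tracks$enhancer,
    dhs = tracks$dhs,
    cpg_island = tracks$cpg,
    sine = tracks$repeats[tracks$repeats$rep_class == "SINE", ],
    line = tracks$repeats[tracks$repeats$rep_class == "LINE", ],
    ltr = tracks$repeats[tracks$repeats$rep_class == "LTR", ],
    dna_repeat = tracks$repeats[tracks$repeats$rep_class == "DNA", ],
    simple_repeat = tracks$repeats[tracks$repeats$rep_class == "Simple_repeat", ],
    low_complexity = tracks$repeats[tracks$repeats$rep_class == "Low_complexity", ],
    satellite = tracks$repeats[tracks$repeats$rep_class == "Satellite", ],
    stop("unknown placement category: ", category))
}

#' Simulate one sample's candidate table
#'
#' Circle lengths are drawn from the group's log-normal mixture; a placement
#' category is sampled per circle from the group weights and the circle is
#' anchored on a uniformly chosen interval of that category (background mass
#' is uniform over the genome). Read-support and coverage fields are drawn
#' so that `pass_fraction` of candidates clears the acceptance criteria;
#' each remaining candidate is given at least one planted violation. The
#' truth vector records which candidates were generated to pass.
#'
#' @param tracks Output of [simulate_genome_and_tracks()].
#' @param config A [simulation_config()].
#' @param group "tumor" or "normal".
#' @param seed Per-sample seed.
#' @return List: `candidates` (data.frame), `truth_pass` (logical),
#'   `mapped_reads` (integer).
#' @export
simulate_sample <- function(tracks, config, group = c("tumor", "normal"),
                            seed) {
  group <- match.arg(group)
  layout <- tracks$layout
  mix <- config$length_mixture[[group]]
  wts <- config$category_weights[[group]]
  with_seed(seed, {
    n <- max(5L, round(config$ecc_per_sample *
                         exp(stats::rnorm(1, 0, config$ecc_dispersion))))
    comp <- sample.int(length(mix$weight), n, replace = TRUE, prob = mix$weight)
    len <- pmax(50, round(stats::rlnorm(n, mix$meanlog[comp], mix$sdlog[comp])))
    cat_draw <- sample(names(wts), n, replace = TRUE, prob = wts)
    chrom <- character(n); start <- numeric(n)
    bg <- which(cat_draw == "background")
    if (length(bg)) {
      ch <- sample(layout$chrom_names, length(bg), replace = TRUE,
                   prob = layout$chrom_lengths / sum(layout$chrom_lengths))
      chrom[bg] <- ch
      start[bg] <- floor(stats::runif(length(bg)) *
                           pmax(1, layout$chrom_lengths[ch] - len[bg]))
    }
    for (cat in setdiff(unique(cat_draw), "background")) {
      idx <- which(cat_draw == cat)
      pool <- placement_pool(tracks, cat)
      j <- sample.int(nrow(pool), length(idx), replace = TRUE)
      anchor <- floor(pool$start[j] +
                        stats::runif(length(idx)) * (pool$end[j] - pool$start[j]))
      s <- anchor - floor(stats::runif(length(idx)) * len[idx])
      ch <- pool$chrom[j]
      chrom[idx] <- ch
      start[idx] <- pmin(pmax(s, 0),
                         pmax(0, layout$chrom_lengths[ch] - len[idx]))
    }
    end <- pmin(start + len, layout$chrom_lengths[chrom])
    truth_pass <- stats::runif(n) < config$pass_fraction
    # support drawn to pass every criterion ...
    split <- 2 + stats::rpois(n, 3)
    disc <- stats::rpois(n, 2)
    disc <- pmax(disc, 3 - split)  # guarantee C2 even for split == 2
    score <- 50 + stats::rexp(n, 1 / 40)
    sdr <- stats::runif(n, 0.40, 0.95)
    edr <- stats::runif(n, 0.40, 0.95)
    unc <- stats::runif(n, 0, 0.09)
    # ... then plant one violation (uniformly chosen criterion) per "fail"
    fail_idx <- which(!truth_pass)
    viol <- sample.int(5, length(fail_idx), replace = TRUE)
    for (k in seq_along(fail_idx)) {
      i <- fail_idx[k]
      switch(viol[k],
             { split[i] <- sample(0:1, 1); disc[i] <- 5 },          # C1
             { split[i] <- 2; disc[i] <- 0 },                       # C2
             score[i] <- stats::runif(1, 0, 49.9),                  # C3
             { sdr[i] <- stats::runif(1, 0, 0.33)                   # C4
               if (stats::runif(1) < 0.5) edr[i] <- stats::runif(1, 0, 0.33) },
             unc[i] <- stats::runif(1, 0.11, 0.5))                  # C5
    }
    candidates <- data.frame(chrom = chrom, start = start, end = end,
                             discordant_reads = disc, split_reads = split,
                             score = score,
                             mean_coverage = stats::runif(n, 5, 60),
                             start_depth_ratio = sdr, end_depth_ratio = edr,
                             uncovered_fraction = unc,
                             stringsAsFactors = FALSE)
    list(candidates = candidates, truth_pass = truth_pass,
         mapped_reads = round(stats::runif(1, config$mapped_reads_range[1],
                                           config$mapped_reads_range[2])))
  })
}

#' Plant disease-free-survival outcomes on a tumor feature matrix
#'
#' Event times follow an exponential proportional-hazards model: each
#' planted feature is standardized across samples and contributes its
#' log-hazard ratio to the linear predictor. Follow-up is administratively
#' censored at the horizon, a configured fraction is randomly censored
#' early, and a lost-to-follow-up fraction gets missing DFS fields.
#'
#' @param feature_matrix Tumor samples x features.
#' @param config A [simulation_config()] (its `survival` entry is used).
#' @param seed Seed for event and censoring draws.
#' @return data.frame sample_id, dfs_time (months), dfs_event (NA when lost).
#' @export
simulate_survival <- function(feature_matrix, config, seed) {
  sv <- config$survival
  missing <- setdiff(names(sv$planted_loghr), colnames(feature_matrix))
  if (length(missing))
    stop("planted features absent from matrix: ",
         paste(missing, collapse = ", "))
  n <- nrow(feature_matrix)
  lp <- rep(0, n)
  for (f in names(sv$planted_loghr)) {
    x <- feature_matrix[, f]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
    lp <- lp + sv$planted_loghr[[f]] * z
  }
  with_seed(seed, {
    t_event <- if (sv$baseline_hazard > 0)
      stats::rexp(n, rate = sv$baseline_hazard * exp(lp))
    else rep(Inf, n)
    t_cens <- rep(sv$horizon_months, n)
    early <- stats::runif(n) < sv$censoring_fraction
    t_cens[early] <- stats::runif(sum(early), 0, sv$horizon_months)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    lost <- stats::runif(n) < sv$lost_fraction
    time[lost] <- NA
    event[lost] <- NA
    data.frame(sample_id = rownames(feature_matrix), dfs_time = time,
               dfs_event = event, stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort
#'
#' Generates the genome and tracks, per-sample candidate tables for the
#' tumor and normal groups, per-sample mapped-read counts, and — after
#' running the accepted candidates through annotation and quantification —
#' planted DFS outcomes for the tumor samples. The `truth` element records
#' the generating parameters and per-candidate pass labels for recovery
#' tests.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `tracks`, `samples` (named list with
#'   `candidates`, `truth_pass`, `mapped_reads`, `group`), `clinical`
#'   (data.frame), `truth` (config + per-sample pass labels).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  tracks <- simulate_genome_and_tracks(config)
  ids <- c(sprintf("T%03d", seq_len(config$n_tumor)),
           sprintf("N%03d", seq_len(config$n_normal)))
  groups <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
  samples <- vector("list", length(ids))
  names(samples) <- ids
  for (i in seq_along(ids)) {
    s <- simulate_sample(tracks, config, groups[i], sub_seed(config$seed, 100 + i))
    s$group <- groups[i]
    samples[[i]] <- s
  }
  catalog <- build_annotation_catalog(tracks$gene_model, tracks$enhancer,
                                      tracks$dhs, tracks$cpg, tracks$repeats,
                                      tracks$layout)
  roster <- default_feature_roster()
  tumor_ids <- ids[groups == "tumor"]
  vecs <- lapply(samples[tumor_ids], function(s) {
    kept <- s$candidates[s$truth_pass, , drop = FALSE]
    quantify_sample(annotate_ecc(kept, catalog), s$mapped_reads, roster)
  })
  surv <- simulate_survival(build_feature_matrix(vecs), config,
                            sub_seed(config$seed, 7))
  clinical <- data.frame(sample_id = ids, tissue_label = groups,
                         dfs_time = NA_real_, dfs_event = NA_integer_,
                         mapped_reads = vapply(samples, function(s)
                           s$mapped_reads, numeric(1)),
                         stringsAsFactors = FALSE)
  m <- match(surv$sample_id, clinical$sample_id)
  clinical$dfs_time[m] <- surv$dfs_time
  clinical$dfs_event[m] <- surv$dfs_event
  structure(list(tracks = tracks, samples = samples, clinical = clinical,
                 truth = list(config = config,
                              pass = lapply(samples, `[[`, "truth_pass"))),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort as a directory tree
#'
#' Emits `chrom.sizes`, `tracks/` (gene model, enhancer/DHS/CpG BED, repeat
#' table), `samples/<id>.tsv` candidate tables, `clinical.tsv`, and
#' `truth.json` (generating parameters and per-candidate pass labels).
#' Output is byte-identical across runs for the same cohort object.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "samples"), showWarnings = FALSE)
  tr <- cohort$tracks
  write_genome_layout(tr$layout, file.path(dir, "chrom.sizes"))
  write_gene_model(tr$gene_model, file.path(dir, "tracks", "genes.tsv"))
  write_interval_track(tr$enhancer, file.path(dir, "tracks", "enhancer.bed"))
  write_interval_track(tr$dhs, file.path(dir, "tracks", "dhs.bed"))
  write_interval_track(tr$cpg, file.path(dir, "tracks", "cpg.bed"))
  write_repeat_table(tr$repeats, file.path(dir, "tracks", "repeats.tsv"))
  for (id in names(cohort$samples))
    write_candidate_table(cohort$samples[[id]]$candidates,
                          file.path(dir, "samples", paste0(id, ".tsv")))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `tracks`, `samples` (candidate data.frames +
#'   mapped_reads), `clinical`.
#' @export
read_cohort <- function(dir) {
  layout <- read_genome_layout(file.path(dir, "chrom.sizes"))
  tracks <- list(
    layout = layout,
    gene_model = read_gene_model(file.path(dir, "tracks", "genes.tsv"), layout),
    enhancer = read_interval_track(file.path(dir, "tracks", "enhancer.bed"), layout),
    dhs = read_interval_track(file.path(dir, "tracks", "dhs.bed"), layout),
    cpg = read_interval_track(file.path(dir, "tracks", "cpg.bed"), layout),
    repeats = read_repeat_table(file.path(dir, "tracks", "repeats.tsv"), layout))
  clinical <- read_clinical_table(file.path(dir, "clinical.tsv"))
  samples <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$sample_id[i]
    list(candidates = read_candidate_table(
      file.path(dir, "samples", paste0(id, ".tsv")), layout),
      mapped_reads = clinical$mapped_reads[i],
      group = clinical$tissue_label[i])
  })
  names(samples) <- clinical$sample_id
  list(tracks = tracks, samples = samples, clinical = clinical)
}
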