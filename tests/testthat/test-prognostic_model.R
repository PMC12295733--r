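test_that("KM estimator gives the closed form without censoring", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # ties collapse into one step
  km <- km_estimate(c(1, 1, 2), c(1, 1, 1))
  expect_equal(km$survival, c(1 / 3, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "no records")
})

test_that("log-rank agrees with survdiff and behaves at the null", {
  set.seed(8)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    tm <- round(rexp(n, ifelse(g == "a", 0.05, 0.08)), 3)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    mine <- logrank_test(tm, ev, g)
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
  # identical copies of the same group
  tm <- c(1, 3, 5, 9); ev <- c(1, 1, 0, 1)
  same <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.999)
  expect_error(logrank_test(tm, rep(0, 4), c("a", "a", "b", "b")), "no events")
})

test_that("log-rank has power against a hazard ratio of 3", {
  hits <- 0
  for (r in 1:30) {
    set.seed(6000 + r)
    tm <- c(rexp(200, 0.02), rexp(200, 0.06))
    g <- rep(c("a", "b"), each = 200)
    res <- logrank_test(tm, rep(1, 400), g)
    if (res$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("optimal cutpoint maximizes the log-rank scan", {
  # block-ordered feature: the returned cutoff separates the two blocs
  set.seed(3)
  v <- c(runif(15, 0, 1), runif(15, 2, 3))
  tm <- c(rexp(15, 0.2), rexp(15, 0.02))
  ev <- rep(1, 30)
  cp <- optimal_cutpoint(v, tm, ev)
  expect_gt(cp$cutoff, 1)
  expect_lt(cp$cutoff, 2)
  expect_equal(cp$n_high, 15)

  expect_error(optimal_cutpoint(rep(1, 30), tm, ev), "no admissible")
  expect_error(optimal_cutpoint(v, tm, rep(0, 30)), "no events")

  # statistic at the returned cutoff >= every admissible candidate,
  # re-evaluated independently through survdiff
  for (r in 1:5) {
    set.seed(40 + r)
    n <- 40
    v <- rnorm(n)
    tm <- rexp(n, 0.05 * exp(0.6 * v))
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0) next
    cp <- optimal_cutpoint(v, tm, ev)
    u <- sort(unique(v))
    mids <- (u[-1] + u[-length(u)]) / 2
    q <- quantile(v, c(0.1, 0.9), names = FALSE)
    mids <- mids[mids >= q[1] & mids <= q[2]]
    mids <- mids[vapply(mids, function(ct)
      sum(v > ct) >= 3 && sum(v <= ct) >= 3, logical(1))]
    ref <- vapply(mids, function(ct)
      survival::survdiff(survival::Surv(tm, ev) ~ (v > ct))$chisq, numeric(1))
    expect_equal(cp$statistic, max(ref), tolerance = 1e-10)
    expect_equal(cp$cutoff, mids[which.max(ref)])
  }
})

test_that("the permutation-corrected p exceeds the naive selection-biased p", {
  set.seed(13)
  n <- 40
  v <- rnorm(n)
  tm <- rexp(n, 0.05)           # feature-independent outcomes
  ev <- rbinom(n, 1, 0.8)
  cp <- optimal_cutpoint(v, tm, ev, permutation_B = 200, seed = 13)
  expect_equal(cp$p_value_flag, "selection-biased")
  expect_gt(cp$p_value_permutation, cp$p_value)
})

test_that("univariate Cox: identical groups, label symmetry, convergence flag", {
  tm <- c(1, 3, 5, 9, 2, 6); ev <- c(1, 1, 0, 1, 1, 0)
  cx <- univariate_cox(rep(c("a", "b"), each = 3), c(tm[1:3], tm[1:3]),
                       c(ev[1:3], ev[1:3]))
  expect_lt(abs(cx$log_hr), 1e-8)
  expect_true(cx$ci_low <= 1 && cx$ci_high >= 1)

  set.seed(2)
  g <- rep(c("a", "b"), each = 50)
  tm <- rexp(100, ifelse(g == "a", 0.02, 0.06))
  fwd <- univariate_cox(g, tm, rep(1, 100))
  rev <- univariate_cox(rev(g), tm, rep(1, 100))
  expect_equal(fwd$hr, 1 / rev$hr, tolerance = 1e-6)

  # complete separation: flagged, not a silent number
  tm <- c(1, 2, 3, 50, 60, 70)
  ev <- c(1, 1, 1, 0, 0, 0)
  cx <- univariate_cox(c("a", "a", "a", "b", "b", "b"), tm, ev)
  expect_false(cx$converged)
})

test_that("survival screening assembles the hazard-ratio table", {
  co <- simulate_cohort(simulation_config(seed = 31, n_tumor = 60,
                                          n_normal = 5,
                                          ecc_per_sample = 200))
  mat <- cohort_feature_matrix(co)
  tum <- co$clinical$tissue_label == "tumor"
  sub <- c("prop_intron", "prop_repeat_all", "prop_exon", "ecc_per_million")
  expect_message(
    scr <- screen_survival_features(mat[tum, sub], co$clinical$dfs_time[tum],
                                    co$clinical$dfs_event[tum]),
    "lost to follow-up")
  expect_equal(scr$feature, sub)
  ok <- !is.na(scr$hr)
  expect_true(all(scr$ci_low[ok] <= scr$hr[ok] & scr$hr[ok] <= scr$ci_high[ok]))
  expect_true(all(scr$logrank_p[ok] >= 0 & scr$logrank_p[ok] <= 1))
})

test_that("prognostic classifier relabels events and reuses the harness", {
  set.seed(44)
  n <- 90
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("s%02d", 1:n),
                                                  paste0("f", 1:6)))
  risk <- X[, 3]
  event <- rbinom(n, 1, plogis(2.5 * risk))
  event[sample(n, 8)] <- NA  # lost to follow-up
  cfg <- harness_config(seed = 44, cv_folds = 5)
  expect_message(rep <- prognostic_classifier(X, event, cfg), "excluded")
  expect_gte(rep$metrics[["auc"]], 0.75)
  expect_error(prognostic_classifier(X[1:4, ], c(1, 1, 1, 1)), ">= 2")
})
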