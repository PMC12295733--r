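# a deterministic fake classifier for metric tests
fake_model <- function(prob_fn, positive = "tumor") {
  structure(list(family = "fake", predict_prob = prob_fn,
                 positive = positive), class = "ecc_classifier")
}

test_that("stratified split partitions the cohort at the configured ratio", {
  labels <- c(rep("tumor", 60), rep("normal", 30))
  cfg <- harness_config(seed = 5)
  sp <- split_cohort(labels, cfg)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_equal(sum(labels[sp$train] == "tumor"), 40)
  expect_equal(sum(labels[sp$train] == "normal"), 20)
  # reproducible from the seed
  expect_identical(split_cohort(labels, cfg), sp)
  expect_false(identical(split_cohort(labels, harness_config(seed = 6)), sp))
  expect_error(split_cohort(c("tumor", rep("normal", 5)), cfg), ">= 2")
})

test_that("rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (r in 1:10) {
    y <- factor(sample(c("a", "b"), 40, replace = TRUE),
                levels = c("a", "b"))
    p <- runif(40)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                          levels = c("a", "b"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(eccProfiler:::auc_score(y, p), ref, tolerance = 1e-12)
  }
})

test_that("a perfectly separable feature yields near-perfect CV AUC", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("normal", "tumor"), each = n / 2)
  X[y == "tumor", 3] <- X[y == "tumor", 3] + 8
  cfg <- harness_config(seed = 3, cv_folds = 5)
  tr <- train_compare(X, y, cfg)
  expect_gte(max(tr$cv_table$cv_auc), 0.99)
  expect_equal(nrow(tr$cv_table), 5)  # all five families scored
})

test_that("the harness is deterministic under a fixed seed", {
  set.seed(7)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c("normal", "tumor"), 25)
  X[y == "tumor", 1] <- X[y == "tumor", 1] + 1
  cfg <- harness_config(seed = 12, cv_folds = 5)
  r1 <- run_diagnostic(X, y, cfg, attribution = FALSE)
  r2 <- run_diagnostic(X, y, cfg, attribution = FALSE)
  expect_identical(r1$cv_table, r2$cv_table)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("permuted labels give chance-level selected CV AUC", {
  co <- simulate_cohort(null_config(seed = 23, n_tumor = 60, n_normal = 60,
                                    ecc_per_sample = 150))
  mat <- cohort_feature_matrix(co)
  set.seed(23)
  y <- sample(co$clinical$tissue_label)
  cfg <- harness_config(seed = 23, cv_folds = 5)
  tr <- train_compare(mat, y, cfg)
  best <- max(tr$cv_table$cv_auc)
  expect_gte(best, 0.38)
  expect_lte(best, 0.62)
})

test_that("held-out metrics follow the confusion-matrix definitions", {
  X <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("normal", "tumor"), each = 10)
  oracle <- fake_model(function(Xn) rep(c(0.1, 0.9), each = 10))
  m <- evaluate_model(oracle, X, y)
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy", "f1",
                          "precision", "auc")]),
               c(1, 1, 1, 1, 1, 1))

  # half the tumor calls flipped: sensitivity 0.5, specificity stays 1
  m <- evaluate_model(fake_model(function(Xn)
    c(rep(0.1, 10), rep(c(0.9, 0.1), 5))), X, y)
  expect_equal(unname(m["sensitivity"]), 0.5)
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(unname(m["precision"]), 1)

  # single-class test set: AUC undefined, other metrics returned
  expect_message(
    m <- evaluate_model(oracle, X[1:10, ], y[1:10]), "single class")
  expect_true(is.na(m["auc"]))
  expect_false(is.na(m["specificity"]))
})

test_that("a coin-flip predictor scores about 0.5 accuracy", {
  n <- 2000
  X <- matrix(0, n, 1, dimnames = list(NULL, "f"))
  y <- rep(c("normal", "tumor"), n / 2)
  set.seed(99)
  p <- runif(n)
  m <- evaluate_model(fake_model(function(Xn) p), X, y)
  expect_lt(abs(m[["accuracy"]] - 0.5), 0.03)
})

test_that("Monte-Carlo Shapley matches the closed form for a linear model", {
  set.seed(14)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  w <- c(0.08, -0.05, 0.02, 0)
  lin <- fake_model(function(Xn) 0.5 + as.numeric(Xn %*% w))
  at <- attribute_features(lin, X[1:8, , drop = FALSE], background = X,
                           n_perm = 200, top_k = 4, seed = 2)
  # for an additive model the Shapley value is w_j * (x_j - E[background_j])
  expected <- sweep(X[1:8, ], 2, colMeans(X)) %*% diag(w)
  expect_lt(max(abs(at$values - expected)), 0.03)
  expect_equal(at$ranking$feature[1], "f1")
})

test_that("the planted informative feature ranks first by attribution", {
  hits <- 0
  for (r in 1:10) {
    set.seed(300 + r)
    n <- 60
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- factor(rep(c("normal", "tumor"), each = n / 2))
    X[y == "tumor", 4] <- X[y == "tumor", 4] + 2.5
    m <- eccProfiler:::fit_classifier(
      "logistic_regression", data.frame(lambda = 0.01), X, y)
    at <- attribute_features(m, X[seq(1, n, 4), , drop = FALSE],
                             background = X, n_perm = 15, top_k = 6,
                             seed = 300 + r)
    if (at$ranking$feature[1] == "f4") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("permutation importance singles out the informative feature", {
  set.seed(5)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("normal", "tumor"), each = n / 2))
  X[y == "tumor", 2] <- X[y == "tumor", 2] + 2
  m <- eccProfiler:::fit_classifier("random_forest",
                                    data.frame(mtry_rule = "sqrt", ntree = 200),
                                    X, y)
  pi <- permutation_importance(m, X, y, seed = 5)
  expect_equal(pi$feature[1], "f2")
})

test_that("a fold holding a single class is reported, not silently fit", {
  X <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c(rep("normal", 10), rep("tumor", 2)))
  expect_error(train_compare(X, y, harness_config(cv_folds = 10)),
               "fold|class")
})
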