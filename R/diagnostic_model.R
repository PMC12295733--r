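#' Default hyperparameter grids for the five-classifier harness
#'
#' Deliberately small grids (every combination is listed in config, none is
#' hard-coded in the fitting path): forest mtry as a function of feature
#' count, ridge penalty for the logistic model, Laplace smoothing for naive
#' Bayes, RBF cost for the SVM, and neighbor count for KNN.
#'
#' @return Named list of data.frames, one per model family.
#' @export
default_grids <- function() {
  list(
    random_forest = data.frame(mtry_rule = c("sqrt", "third"), ntree = 300,
                               stringsAsFactors = FALSE),
    logistic_regression = data.frame(lambda = c(0.001, 0.01, 0.1, 1)),
    naive_bayes = data.frame(laplace = c(0, 1)),
    svm = data.frame(cost = c(0.5, 2, 8)),
    knn = data.frame(k = c(5, 9, 15)))
}

#' Configuration for the diagnostic model harness
#'
#' @param split_ratio Training fraction of the stratified split (default
#'   2/3, i.e. a 2:1 train:test split).
#' @param cv_folds Stratified cross-validation folds (default 10).
#' @param seed Seed controlling split, folds, and stochastic fits.
#' @param models Model families to compare, in tie-break priority order.
#' @param grids Hyperparameter grids as from [default_grids()].
#' @param attribution_top_k Features reported by the attribution stage.
#' @param standardize Standardize features (train mean/SD) for the linear,
#'   margin and neighbor models; tree and Bayes models see raw values.
#' @return A `harness_config` list.
#' @export
harness_config <- function(split_ratio = 2 / 3, cv_folds = 10, seed = 1L,
                           models = c("random_forest", "logistic_regression",
                                      "naive_bayes", "svm", "knn"),
                           grids = default_grids(),
                           attribution_top_k = 10, standardize = TRUE) {
  stopifnot(split_ratio > 0, split_ratio < 1, cv_folds >= 2,
            all(models %in% names(default_grids())))
  structure(list(split_ratio = split_ratio, cv_folds = cv_folds,
                 seed = as.integer(seed), models = models, grids = grids,
                 attribution_top_k = attribution_top_k,
                 standardize = standardize),
            class = "harness_config")
}

# rank-based AUC of the positive class (second factor level);
# cross-checked against pROC in the test-suite
auc_score <- function(y, p) {
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split
#'
#' @param labels Factor/character class labels.
#' @param config A [harness_config()].
#' @return List with integer `train` and `test` index vectors (disjoint,
#'   exhaustive, reproducible from the config seed).
#' @export
split_cohort <- function(labels, config = harness_config()) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 samples to split")
  with_seed(sub_seed(config$seed, 11), {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      n_tr <- round(length(idx) * config$split_ratio)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, idx[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = sort(setdiff(seq_along(labels), train)))
  })
}

# stratified fold assignment
make_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

resolve_mtry <- function(rule, p) {
  switch(rule, sqrt = max(1L, floor(sqrt(p))), third = max(1L, floor(p / 3)),
         stop("unknown mtry rule: ", rule))
}

# fit one family with one parameter row; returns a closure-based wrapper
# exposing predict_prob(Xnew) for the positive (second-level) class
fit_classifier <- function(family, params, X, y, standardize = TRUE) {
  center <- NULL; scale <- NULL
  if (standardize && family %in% c("logistic_regression", "svm", "knn")) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  prep <- function(Xn) {
    if (is.null(center)) Xn
    else sweep(sweep(Xn, 2, center), 2, scale, "/")
  }
  pos <- levels(y)[2]
  predict_prob <- switch(
    family,
    random_forest = {
      fit <- randomForest::randomForest(
        x = X, y = y, ntree = params$ntree,
        mtry = resolve_mtry(params$mtry_rule, ncol(X)))
      function(Xn) unname(stats::predict(fit, prep(Xn), type = "prob")[, pos])
    },
    logistic_regression = {
      # glmnet warns on every fit with a small class; routine here for the
      # low-event prognostic folds, so silence that one message
      fit <- withCallingHandlers(
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = c(params$lambda * c(4, 2), params$lambda)),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      function(Xn) as.numeric(stats::predict(fit, prep(Xn), s = params$lambda,
                                             type = "response"))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(X, y, laplace = params$laplace)
      # a feature constant within a class would give a zero Gaussian SD and
      # NaN densities at prediction; floor the SDs instead
      for (t in names(fit$tables))
        fit$tables[[t]][, 2] <- pmax(fit$tables[[t]][, 2], 1e-9)
      function(Xn) {
        p <- stats::predict(fit, as.data.frame(prep(Xn)), type = "raw")[, pos]
        unname(p)
      }
    },
    svm = {
      fit <- e1071::svm(X, y, kernel = "radial", cost = params$cost,
                        scale = FALSE)
      function(Xn) {
        dv <- attr(stats::predict(fit, prep(Xn), decision.values = TRUE),
                   "decision.values")
        # decision value is positive for the class named first in the colname
        d <- as.numeric(dv[, 1])
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        if (first == pos) stats::plogis(d) else stats::plogis(-d)
      }
    },
    knn = {
      Xtr <- X; ytr <- y
      kk <- min(params$k, nrow(X) - 1L)  # k cannot exceed the training size
      function(Xn) {
        # knn breaks distance/vote ties randomly; pin them for reproducibility
        pred <- with_seed(20240601L,
                          class::knn(Xtr, prep(Xn), ytr, k = kk, prob = TRUE))
        pr <- attr(pred, "prob")
        ifelse(pred == pos, pr, 1 - pr)
      }
    },
    stop("unknown model family: ", family))
  structure(list(family = family, params = params, predict_prob = predict_prob,
                 positive = pos), class = "ecc_classifier")
}

# mean CV AUC of one (family, params) combination over prebuilt folds
cv_auc <- function(family, params, X, y, fold, standardize, seed) {
  k <- max(fold)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      stop("a CV fold contains one class; use a larger cohort or fewer folds")
    with_seed(sub_seed(seed, 1000 + f), {
      m <- fit_classifier(family, params, X[tr, , drop = FALSE],
                          droplevels(y[tr]), standardize)
      aucs[f] <- auc_score(y[!tr], m$predict_prob(X[!tr, , drop = FALSE]))
    })
  }
  mean(aucs)
}

#' Grid-searched five-model comparison on the training set
#'
#' For each configured family, every grid row is scored by mean AUC over
#' stratified `cv_folds` cross-validation; the family with the highest
#' cross-validated AUC (ties broken toward the earlier family in the config
#' order) is refit on the full training set with its best parameters.
#'
#' @param X Training feature matrix.
#' @param y Training labels: factor whose second level is the positive
#'   class (coerced from character with sorted levels).
#' @param config A [harness_config()].
#' @return List: `cv_table` (family, best parameters as string, cv_auc),
#'   `best_family`, `model` (fitted wrapper).
#' @export
train_compare <- function(X, y, config = harness_config()) {
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2) stop("train_compare needs exactly 2 classes")
  fold <- make_folds(y, config$cv_folds, sub_seed(config$seed, 22))
  rows <- list()
  best <- list()
  for (family in config$models) {
    grid <- config$grids[[family]]
    scores <- vapply(seq_len(nrow(grid)), function(g)
      cv_auc(family, grid[g, , drop = FALSE], X, y, fold,
             config$standardize, sub_seed(config$seed, 500 + g)),
      numeric(1))
    gbest <- which.max(scores)
    best[[family]] <- grid[gbest, , drop = FALSE]
    rows[[family]] <- data.frame(
      family = family,
      best_params = paste(sprintf("%s=%s", names(grid),
                                  unlist(grid[gbest, , drop = FALSE])),
                          collapse = ","),
      cv_auc = scores[gbest], stringsAsFactors = FALSE)
  }
  cv_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  best_family <- cv_table$family[which.max(cv_table$cv_auc)]
  model <- with_seed(sub_seed(config$seed, 33),
                     fit_classifier(best_family, best[[best_family]], X, y,
                                    config$standardize))
  list(cv_table = cv_table, best_family = best_family, model = model)
}

#' Held-out classification metrics
#'
#' Class calls at the 0.5 probability threshold; AUC is threshold-free.
#' With a single-class test set AUC is NA (with a message) while the other
#' metrics are still returned.
#'
#' @param model Fitted wrapper from [train_compare()] / `fit_classifier`.
#' @param X Test features.
#' @param y Test labels (factor or character; positive = second level).
#' @return Named numeric vector: sensitivity, specificity, precision, f1,
#'   accuracy, auc.
#' @export
evaluate_model <- function(model, X, y) {
  if (!is.factor(y)) y <- factor(y)
  p <- model$predict_prob(X)
  pos <- model$positive
  truth <- y == pos
  call <- p >= 0.5
  tp <- sum(call & truth); fp <- sum(call & !truth)
  fn <- sum(!call & truth); tn <- sum(!call & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- auc_score(factor(truth, levels = c(FALSE, TRUE)), p)
  if (is.na(auc)) message("test set has a single class; AUC undefined")
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    accuracy = (tp + tn) / length(y), auc = auc)
}

#' Monte-Carlo Shapley feature attribution
#'
#' Sampling estimator of per-sample Shapley values for the model's positive
#' class probability: for each instance and sampled feature permutation, a
#' background row is drawn and features are switched from background to
#' instance values in permutation order; the successive prediction
#' differences are the per-feature contributions, which average (over
#' permutations and background draws) to Shapley values under the
#' interventional feature-removal convention. Within one permutation the
#' contributions sum exactly to f(x) - f(z).
#'
#' @param model Fitted wrapper.
#' @param X Instances to explain (matrix).
#' @param background Background data (default `X`).
#' @param n_perm Sampled permutations per instance (default 20).
#' @param top_k Features to report, ranked by mean absolute value.
#' @param seed Seed for permutation and background draws.
#' @return List: `ranking` (data.frame feature, mean_abs, mean_signed for
#'   the top_k), `values` (instances x features Shapley matrix).
#' @export
attribute_features <- function(model, X, background = X, n_perm = 20,
                               top_k = 10, seed = 1L) {
  p <- ncol(X)
  phi <- matrix(0, nrow(X), p, dimnames = list(rownames(X), colnames(X)))
  with_seed(sub_seed(seed, 44), {
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      for (m in seq_len(n_perm)) {
        z <- background[sample.int(nrow(background), 1), ]
        ord <- sample.int(p)
        # rows: background -> progressively switched to x along ord
        walk <- matrix(rep(z, p + 1), nrow = p + 1, byrow = TRUE,
                       dimnames = list(NULL, colnames(X)))
        for (s in seq_len(p))
          walk[(s + 1):(p + 1), ord[s]] <- x[ord[s]]
        preds <- model$predict_prob(walk)
        phi[i, ord] <- phi[i, ord] + diff(preds) / n_perm
      }
    }
  })
  mean_abs <- colMeans(abs(phi))
  ord <- order(mean_abs, decreasing = TRUE)[seq_len(min(top_k, p))]
  list(ranking = data.frame(feature = colnames(X)[ord],
                            mean_abs = mean_abs[ord],
                            mean_signed = colMeans(phi)[ord],
                            row.names = NULL, stringsAsFactors = FALSE),
       values = phi)
}

#' Permutation feature importance (attribution fallback)
#'
#' Mean held-out AUC drop when one feature column is permuted; a cheaper,
#' model-agnostic alternative to the Shapley estimator, flagged as such in
#' pipeline reports.
#'
#' @param model Fitted wrapper.
#' @param X,y Evaluation data.
#' @param n_rep Permutations per feature (default 5).
#' @param seed Seed.
#' @return data.frame feature, auc_drop, sorted decreasing.
#' @export
permutation_importance <- function(model, X, y, n_rep = 5, seed = 1L) {
  if (!is.factor(y)) y <- factor(y)
  base <- auc_score(y, model$predict_prob(X))
  with_seed(sub_seed(seed, 55), {
    drop <- vapply(seq_len(ncol(X)), function(j) {
      d <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        d[r] <- base - auc_score(y, model$predict_prob(Xp))
      }
      mean(d)
    }, numeric(1))
  })
  out <- data.frame(feature = colnames(X), auc_drop = drop,
                    stringsAsFactors = FALSE)
  out[order(out$auc_drop, decreasing = TRUE), , drop = FALSE]
}

#' Run the full diagnostic harness
#'
#' Stratified 2:1 split, grid-searched five-model comparison on the
#' training set, held-out metrics for the selected model, and top-k Shapley
#' attribution computed on the test instances against a training-set
#' background.
#'
#' @param mat Feature matrix (samples x features).
#' @param labels Class labels per sample (positive = second sorted level,
#'   e.g. "tumor" against "normal").
#' @param config A [harness_config()].
#' @param attribution Compute Shapley attribution (default TRUE; the slow
#'   part of the report).
#' @return List: `split`, `cv_table`, `best_family`, `model`, `metrics`,
#'   `attribution` (or NULL).
#' @export
run_diagnostic <- function(mat, labels, config = harness_config(),
                           attribution = TRUE) {
  y <- factor(as.character(labels))
  sp <- split_cohort(y, config)
  tr <- train_compare(mat[sp$train, , drop = FALSE], y[sp$train], config)
  metrics <- evaluate_model(tr$model, mat[sp$test, , drop = FALSE], y[sp$test])
  attr_out <- NULL
  if (attribution)
    attr_out <- attribute_features(tr$model, mat[sp$test, , drop = FALSE],
                                   background = mat[sp$train, , drop = FALSE],
                                   top_k = config$attribution_top_k,
                                   seed = config$seed)
  list(split = sp, cv_table = tr$cv_table, best_family = tr$best_family,
       model = tr$model, metrics = metrics, attribution = attr_out)
}
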