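#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over the standard survival machinery returning the step
#' function as a plain data.frame for export and plotting.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = recurrence/death, 0 = censored).
#' @return data.frame time, n_risk, n_event, n_censor, survival.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom chi-square comparing the event processes
#' of two groups under right censoring, computed directly from the risk-set
#' tables (hypergeometric variance). The same statistic drives the optimal
#' cutpoint scan; the test-suite cross-checks it against the survival
#' package.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level group labels.
#' @return List: `statistic` (chi-square), `p_value` (two-sided, 1 df),
#'   `observed`, `expected` (per-group event counts for the first group).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(factor(as.character(group)))
  if (length(unique(g)) != 2L) stop("log-rank needs exactly 2 groups")
  if (sum(event) == 0L) stop("log-rank undefined with no events")
  stat <- logrank_stat(time, event, g == 1L)
  list(statistic = stat$chisq,
       p_value = stats::pchisq(stat$chisq, df = 1, lower.tail = FALSE),
       observed = stat$observed, expected = stat$expected)
}

# core statistic: `in1` flags membership of group 1
logrank_stat <- function(time, event, in1) {
  et <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq, observed = O, expected = E)
}

#' Optimal log-rank cutpoint for a continuous feature
#'
#' Exhaustive scan over admissible cutoffs — midpoints between consecutive
#' sorted unique feature values whose quantile lies within `bounds` and
#' whose high/low groups both hold at least `min_group_size` samples —
#' returning the cutoff maximizing the two-group log-rank statistic (ties
#' broken toward the lower cutoff). The reported p-value is the naive
#' log-rank p at the selected cutoff and is flagged selection-biased: the
#' maximization inflates it. An optional permutation correction (feature
#' values permuted against fixed outcomes) estimates the selection-adjusted
#' p.
#'
#' @param values Feature values.
#' @param time,event Survival records.
#' @param bounds Quantile window for candidate cutoffs (default 10th-90th
#'   percentile).
#' @param min_group_size Minimum size of each side (default 3).
#' @param permutation_B Permutations for the corrected p (0 = skip,
#'   default 0; 1000 is a sensible choice when used).
#' @param seed Seed for the permutation correction.
#' @return List: `cutoff`, `statistic`, `p_value` (naive),
#'   `p_value_flag = "selection-biased"`, `n_high`, `n_low`, `n_candidates`,
#'   and `p_value_permutation` when requested.
#' @export
optimal_cutpoint <- function(values, time, event, bounds = c(0.1, 0.9),
                             min_group_size = 3, permutation_B = 0,
                             seed = 1L) {
  keep <- !is.na(values) & !is.na(time) & !is.na(event)
  values <- values[keep]; time <- time[keep]; event <- event[keep]
  if (length(values) < 2 * min_group_size)
    stop("need at least 2*min_group_size samples")
  if (sum(event) == 0) stop("no events; cutpoint scan undefined")
  cand <- admissible_cutoffs(values, bounds, min_group_size)
  if (length(cand) == 0L) stop("no admissible cutoff for this feature")
  stats_at <- vapply(cand, function(ct)
    logrank_stat(time, event, values > ct)$chisq, numeric(1))
  best <- which.max(stats_at)  # which.max takes the first = lowest cutoff
  cutoff <- cand[best]
  res <- list(cutoff = cutoff, statistic = stats_at[best],
              p_value = stats::pchisq(stats_at[best], 1, lower.tail = FALSE),
              p_value_flag = "selection-biased",
              n_high = sum(values > cutoff), n_low = sum(values <= cutoff),
              n_candidates = length(cand))
  if (permutation_B > 0) {
    obs <- stats_at[best]
    with_seed(sub_seed(seed, 66), {
      exceed <- 0L
      for (b in seq_len(permutation_B)) {
        vp <- sample(values)
        cb <- admissible_cutoffs(vp, bounds, min_group_size)
        if (length(cb) == 0L) next
        mx <- max(vapply(cb, function(ct)
          logrank_stat(time, event, vp > ct)$chisq, numeric(1)))
        if (mx >= obs) exceed <- exceed + 1L
      }
      res$p_value_permutation <- (exceed + 1) / (permutation_B + 1)
    })
  }
  res
}

admissible_cutoffs <- function(values, bounds, min_group_size) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(numeric(0))
  mid <- (u[-1] + u[-length(u)]) / 2
  q <- stats::quantile(values, bounds, names = FALSE, type = 7)
  ok <- mid >= q[1] & mid <= q[2]
  sizes_ok <- vapply(mid, function(ct)
    sum(values > ct) >= min_group_size && sum(values <= ct) >= min_group_size,
    logical(1))
  mid[ok & sizes_ok]
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron handling of tied event times; reports
#' the hazard ratio of `x` (binary group or continuous feature) with Wald
#' 95% confidence interval and p-value. Non-convergence or an unbounded
#' estimate (complete separation of events) is reported distinctly via
#' `converged = FALSE` instead of a silent number.
#'
#' @param x Covariate: two-level group labels or numeric feature.
#' @param time,event Survival records.
#' @return List: `hr`, `ci_low`, `ci_high`, `p_value`, `log_hr`, `se`,
#'   `converged`.
#' @export
univariate_cox <- function(x, time, event) {
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event) == 0) stop("no events; Cox model undefined")
  if (!is.numeric(x)) {
    f <- factor(as.character(x))
    if (nlevels(f) != 2L) stop("grouping covariate must have 2 levels")
    x <- as.numeric(f) - 1
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"))
      attr(f, "warned") <- conditionMessage(w)
      f
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  warned <- !is.null(attr(fit, "warned"))
  converged <- is.finite(beta) && is.finite(se) && se < 50 && !warned
  z <- beta / se
  list(hr = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(z)), log_hr = beta, se = se,
       converged = converged)
}

#' Screen features for survival association
#'
#' Runs the optimal-cutpoint Kaplan-Meier/log-rank procedure for every
#' feature and the univariate Cox fit on the resulting high/low labels,
#' assembling a hazard-ratio table (feature, HR, CI, p). Samples with
#' missing DFS fields (lost to follow-up) are dropped with a message.
#'
#' @param mat Feature matrix of tumor samples.
#' @param time,event Survival records aligned with `mat` rows (NA = lost to
#'   follow-up).
#' @param p_threshold Screening threshold on the naive log-rank p
#'   (default 0.05).
#' @param adjust "none" (default) or "BH" on the log-rank p-values.
#' @param ... Passed to [optimal_cutpoint()].
#' @return data.frame: feature, cutoff, logrank_stat, logrank_p, hr,
#'   ci_low, ci_high, cox_p, cox_converged, significant.
#' @export
screen_survival_features <- function(mat, time, event, p_threshold = 0.05,
                                     adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep))
    message(sum(!keep), " samples lost to follow-up excluded from survival screening")
  mat <- mat[keep, , drop = FALSE]; time <- time[keep]; event <- event[keep]
  rows <- lapply(colnames(mat), function(f) {
    cp <- tryCatch(optimal_cutpoint(mat[, f], time, event, ...),
                   error = function(e) NULL)
    if (is.null(cp))
      return(data.frame(feature = f, cutoff = NA_real_,
                        logrank_stat = NA_real_, logrank_p = NA_real_,
                        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        cox_p = NA_real_, cox_converged = NA,
                        stringsAsFactors = FALSE))
    cx <- univariate_cox(as.numeric(mat[, f] > cp$cutoff), time, event)
    data.frame(feature = f, cutoff = cp$cutoff, logrank_stat = cp$statistic,
               logrank_p = cp$p_value, hr = cx$hr, ci_low = cx$ci_low,
               ci_high = cx$ci_high, cox_p = cx$p_value,
               cox_converged = cx$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p <- if (adjust == "BH") stats::p.adjust(out$logrank_p, "BH") else out$logrank_p
  out$significant <- !is.na(p) & p < p_threshold
  out
}

#' DFS-event classifier on tumor samples
#'
#' Reuses the diagnostic harness with the binary DFS event (1 = recurrence
#' or death within follow-up) as the label; lost-to-follow-up samples are
#' excluded with a logged count.
#'
#' @param mat Feature matrix of tumor samples.
#' @param event Event indicators aligned with rows (NA = lost).
#' @param config A [harness_config()].
#' @param attribution Compute Shapley attribution (default FALSE).
#' @return As [run_diagnostic()].
#' @export
prognostic_classifier <- function(mat, event, config = harness_config(),
                                  attribution = FALSE) {
  keep <- !is.na(event)
  if (any(!keep))
    message(sum(!keep), " samples lost to follow-up excluded from prognostic model")
  mat <- mat[keep, , drop = FALSE]
  y <- factor(ifelse(event[keep] == 1, "event", "censored"),
              levels = c("censored", "event"))
  if (sum(y == "event") < 2 || sum(y == "censored") < 2)
    stop("need >= 2 events and >= 2 non-events")
  run_diagnostic(mat, y, config, attribution = attribution)
}
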