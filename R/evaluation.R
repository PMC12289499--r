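#' DeLong AUC estimate with variance and confidence interval
#'
#' Computes the area under the ROC curve via the Mann-Whitney kernel
#' (ties count 1/2) together with its DeLong variance from the structural
#' components of the statistic, and a normal-approximation confidence
#' interval truncated to \[0, 1\].
#'
#' @param scores Numeric score per sample (higher = more lesion-like).
#' @param labels 0/1 outcome per sample.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `auc`, `variance`, `conf_low`, `conf_high`,
#'   `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels, conf_level = 0.95) {
  labels <- assert_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  comp <- delong_components(scores, labels)
  m <- length(comp$v10); n <- length(comp$v01)
  v <- if (m > 1 && n > 1) var(comp$v10) / m + var(comp$v01) / n else 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  fast_tibble(auc = comp$auc, variance = v,
              conf_low = max(0, comp$auc - z * sqrt(v)),
              conf_high = min(1, comp$auc + z * sqrt(v)),
              n_pos = m, n_neg = n)
}

# Structural components: v10[i] = P(X_i > Y) + P(X_i = Y)/2 over negatives,
# v01[j] analogous over positives; computed with midranks.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01)
}

#' DeLong comparison of two AUCs
#'
#' Two-sided z-test on the difference of two AUCs. The unpaired variant
#' (independent sample sets, e.g. a train vs. a test split) adds the two
#' DeLong variances; the paired variant (two scores on the same samples)
#' uses the covariance of the structural components.
#'
#' @param scores_a,scores_b Scores under the two models/sets.
#' @param labels_a Labels for `scores_a` (and for `scores_b` when paired).
#' @param labels_b Labels for `scores_b`; ignored when `paired = TRUE`.
#' @param paired Are the two score vectors computed on the same samples?
#' @return One-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, labels_a, scores_b, labels_b = NULL,
                           paired = FALSE) {
  labels_a <- assert_binary_labels(labels_a, "labels_a")
  if (paired) {
    if (!is.null(labels_b) && !identical(as.integer(labels_b), labels_a)) {
      abort("paired comparison requires identical samples (labels differ)")
    }
    if (length(scores_a) != length(scores_b)) {
      abort("paired comparison requires identical samples (lengths differ)")
    }
    ca <- delong_components(scores_a, labels_a)
    cb <- delong_components(scores_b, labels_a)
    m <- length(ca$v10); n <- length(ca$v01)
    s10 <- cov(cbind(ca$v10, cb$v10)); s01 <- cov(cbind(ca$v01, cb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    auc_a <- ca$auc; auc_b <- cb$auc
  } else {
    labels_b <- assert_binary_labels(labels_b, "labels_b")
    a <- auc_delong(scores_a, labels_a); b <- auc_delong(scores_b, labels_b)
    v <- a$variance + b$variance
    auc_a <- a$auc; auc_b <- b$auc
  }
  d <- auc_a - auc_b
  z <- if (d == 0) 0 else if (v <= 0) sign(d) * Inf else d / sqrt(v)
  fast_tibble(auc_a = auc_a, auc_b = auc_b, z = z,
              p_value = 2 * pnorm(-abs(z)))
}

#' Two-sample Monte-Carlo permutation test
#'
#' Tests whether a score differs between the two label groups. The
#' statistic is the absolute difference of group means; the p-value uses
#' the add-one correction `p = (1 + #{extreme}) / (B + 1)`, so it lives in
#' `[1/(B+1), 1]`.
#'
#' @param values Numeric values (e.g. a Radiomics Score per sample).
#' @param labels 0/1 group per sample.
#' @param n_permutations Number of Monte-Carlo label permutations `B`.
#' @param seed RNG seed for the permutation draws.
#' @return The p-value, a bare number.
#' @export
permutation_test_scores <- function(values, labels, n_permutations = 9999,
                                    seed = 1L) {
  labels <- assert_binary_labels(labels)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  stopifnot(length(values) == length(labels), !anyNA(values))
  n <- length(values); m <- sum(labels == 1)
  tot <- sum(values)
  stat <- function(s1) abs(s1 / m - (tot - s1) / (n - m))
  obs <- stat(sum(values[labels == 1]))
  perm <- with_seed(seed, vapply(
    seq_len(n_permutations),
    function(i) stat(sum(values[sample.int(n, m)])),
    numeric(1)))
  (1 + sum(perm >= obs - 1e-12)) / (n_permutations + 1)
}

#' Youden-index operating point
#'
#' Sweeps cutoffs over midpoints of adjacent sorted unique scores
#' (prediction rule: positive iff `score >= cutoff`) and returns the
#' cutoff maximizing J = sensitivity + specificity - 1. Ties in J are
#' broken toward the higher-specificity (larger) cutoff, matching the
#' preference for minimizing misdiagnosis of non-dominant adrenals.
#'
#' @inheritParams auc_delong
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `degenerate`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    return(tibble(cutoff = u[1], sensitivity = 1, specificity = 0,
                  youden_j = 0, degenerate = TRUE))
  }
  cuts <- (u[-1] + u[-length(u)]) / 2
  m <- sum(labels == 1); n <- sum(labels == 0)
  sens <- vapply(cuts, function(c) sum(scores >= c & labels == 1) / m, numeric(1))
  spec <- vapply(cuts, function(c) sum(scores < c & labels == 0) / n, numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(spec[best] + 1e-9 * cuts[best])]
  tibble(cutoff = cuts[pick], sensitivity = sens[pick],
         specificity = spec[pick], youden_j = j[pick], degenerate = FALSE)
}

#' Confusion-matrix metric suite
#'
#' Core classification rates from the four confusion counts. Ratios with a
#' zero denominator are reported as `NA` (undefined), never as 0.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `error_rate`, `recall`, `f1`, `kappa`, `ppv`, `npv` and the counts.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  n <- tp + fn + fp + tn
  if (n == 0) abort("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn); spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp); npv <- safe_div(tn, tn + fn)
  acc <- (tp + tn) / n
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  tibble(sensitivity = sens, specificity = spec, accuracy = acc,
         error_rate = 1 - acc, recall = sens, f1 = f1, kappa = kappa,
         ppv = ppv, npv = npv, tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Performance report at a stated cutoff
#'
#' Dichotomizes scores at `cutoff` (positive iff `score >= cutoff`) and
#' combines the confusion-matrix suite with the DeLong AUC and its CI.
#'
#' @inheritParams auc_delong
#' @param cutoff Operating cutoff on the score scale.
#' @return One-row tibble (see [confusion_metrics()]) plus `auc`,
#'   `auc_conf_low`, `auc_conf_high`, `cutoff`.
#' @export
performance_report <- function(scores, labels, cutoff, conf_level = 0.95) {
  labels <- assert_binary_labels(labels)
  pred <- as.integer(scores >= cutoff)
  cm <- confusion_metrics(sum(pred == 1 & labels == 1),
                          sum(pred == 0 & labels == 1),
                          sum(pred == 1 & labels == 0),
                          sum(pred == 0 & labels == 0))
  a <- auc_delong(scores, labels, conf_level)
  bind_cols(tibble(auc = a$auc, auc_conf_low = a$conf_low,
                   auc_conf_high = a$conf_high, cutoff = cutoff), cm)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups samples into `g` deciles of predicted risk (equal-frequency,
#' ties kept together) and compares observed versus expected event counts;
#' the statistic is referred to a chi-square with `g - 2` degrees of
#' freedom.
#'
#' @param probabilities Predicted event probabilities in (0, 1).
#' @param outcomes 0/1 observed outcomes.
#' @param g Number of risk groups (default 10).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`.
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, g = 10) {
  outcomes <- assert_binary_labels(outcomes, "outcomes")
  if (any(probabilities <= 0 | probabilities >= 1)) {
    abort("probabilities must lie strictly in (0, 1)")
  }
  if (g < 3) abort("`g` must be >= 3")
  n <- length(probabilities)
  if (n < g) abort("need at least `g` samples")
  brk <- unique(quantile(probabilities, seq(0, 1, length.out = g + 1),
                         type = 7))
  if (length(brk) - 1 < g) {
    warn(sprintf("ties reduced the risk groups from %d to %d", g, length(brk) - 1))
  }
  grp <- cut(probabilities, brk, include.lowest = TRUE)
  tab <- tibble(grp = grp, p = probabilities, y = outcomes) |>
    group_by(.data$grp) |>
    summarise(n_g = n(), obs = sum(.data$y), exp = sum(.data$p),
              .groups = "drop")
  stat <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n_g)))
  df <- nrow(tab) - 2
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         n_groups = nrow(tab))
}

#' Calibration bins
#'
#' Equal-frequency bins of predicted probability with per-bin mean
#' prediction and observed event rate, the raw material of a calibration
#' curve.
#'
#' @inheritParams hosmer_lemeshow
#' @param n_bins Number of bins (default 10).
#' @return Tibble with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed_rate`.
#' @export
calibration_bins <- function(probabilities, outcomes, n_bins = 10) {
  outcomes <- assert_binary_labels(outcomes, "outcomes")
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  n <- length(probabilities)
  if (n < n_bins) abort("fewer samples than bins")
  ord <- order(probabilities)
  bin <- ceiling(seq_along(ord) / (n / n_bins))
  tibble(bin = bin, p = probabilities[ord], y = outcomes[ord]) |>
    group_by(.data$bin) |>
    summarise(n = n(), mean_predicted = mean(.data$p),
              observed_rate = mean(.data$y), .groups = "drop")
}

#' Decision-curve analysis
#'
#' Net benefit of treating at each threshold probability `t`:
#' `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)` with predictions
#' `1{probability >= t}`, alongside the treat-all and treat-none
#' references.
#'
#' @inheritParams hosmer_lemeshow
#' @param thresholds Threshold probability grid in (0, 1).
#' @return Tibble of class `dca_curve`: one row per threshold with
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, outcomes,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  outcomes <- assert_binary_labels(outcomes, "outcomes")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly in (0, 1)")
  }
  n <- length(outcomes); prev <- mean(outcomes)
  rows <- purrr::map_dfr(thresholds, function(t) {
    pred <- probabilities >= t
    tibble(threshold = t,
           net_benefit = sum(pred & outcomes == 1) / n -
             sum(pred & outcomes == 0) / n * t / (1 - t),
           treat_all = prev - (1 - prev) * t / (1 - t),
           treat_none = 0)
  })
  structure(rows, class = c("dca_curve", class(rows)))
}

#' ROC curve points
#'
#' Sensitivity/specificity at every distinct cutoff, for plotting and
#' export (one row per threshold, tidy layout).
#'
#' @inheritParams auc_delong
#' @return Tibble of class `roc_points`: `cutoff`, `sensitivity`,
#'   `specificity`, plus attribute-free `auc` column repeated per row.
#' @export
roc_points <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  u <- sort(unique(scores))
  cuts <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  m <- sum(labels == 1); n <- sum(labels == 0)
  rows <- purrr::map_dfr(cuts, function(c) {
    tibble(cutoff = c,
           sensitivity = sum(scores >= c & labels == 1) / m,
           specificity = sum(scores < c & labels == 0) / n)
  })
  rows$auc <- auc_delong(scores, labels)$auc
  structure(rows, class = c("roc_points", class(rows)))
}
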