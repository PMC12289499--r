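#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA mean squares: with `n` subjects and
#' `k` raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the subject, rater, and residual mean squares.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns.
#' @return The ICC estimate (a bare number in \[-1, 1\]).
#' @export
icc_21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) abort("ratings must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(1)
  (msr - mse) / denom
}

#' Reproducibility (ICC) filter over two delineation replicates
#'
#' Drops radiomic features whose ICC(2,1) between the two raters'
#' replicate extractions falls below `threshold` (default 0.75, the common
#' radiomics reproducibility convention), removing features whose values
#' depend too strongly on who drew the region of interest.
#'
#' Two retention modes are supported: `"threshold"` (default) keeps
#' features with ICC at or above `threshold`; `"test"` keeps features
#' whose between-subject variance is significant (one-sided F test of
#' MSR/MSE at `alpha`), i.e. whose variability between delineations is
#' small relative to the between-subject spread.
#'
#' @param replicate_a,replicate_b Feature tables from the two raters;
#'   identical sample ids and feature names required.
#' @param threshold Minimum ICC to retain a feature (threshold mode).
#' @param method Retention rule, `"threshold"` or `"test"`.
#' @param alpha Significance level of the F test (test mode).
#' @return List with `retained` (feature names) and `report`, a tibble
#'   (`feature`, `class`, `icc`, `retained`, ...) covering every feature.
#' @export
icc_filter <- function(replicate_a, replicate_b, threshold = 0.75,
                       method = c("threshold", "test"), alpha = 0.05) {
  method <- match.arg(method)
  a <- validate_feature_table(replicate_a, require_label = FALSE)
  b <- validate_feature_table(replicate_b, require_label = FALSE)
  if (!setequal(a$sample_id, b$sample_id)) {
    abort("replicates must cover the same sample ids")
  }
  if (!setequal(feature_names(a), feature_names(b))) {
    abort("replicates must cover the same features")
  }
  b <- b[match(a$sample_id, b$sample_id), ]
  feats <- feature_names(a)
  stats <- purrr::map_dfr(feats, function(f) {
    m <- cbind(a[[f]], b[[f]])
    if (var(m[, 1]) == 0 && var(m[, 2]) == 0) {
      return(tibble(icc = 1, f_p = 0))
    }
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    row_m <- rowMeans(m); col_m <- colMeans(m)
    msr <- k * sum((row_m - grand)^2) / (n - 1)
    mse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) +
                  grand)^2) / ((n - 1) * (k - 1))
    tibble(icc = icc_21(m),
           f_p = if (mse == 0) 0 else
             stats::pf(msr / mse, n - 1, (n - 1) * (k - 1),
                       lower.tail = FALSE))
  })
  retained <- if (method == "threshold") stats$icc >= threshold
              else stats$f_p < alpha
  report <- tibble(feature = feats, class = sub("_.*$", "", feats),
                   icc = stats$icc, f_p = stats$f_p, retained = retained,
                   threshold = threshold, method = method,
                   icc_form = "ICC(2,1)")
  list(retained = report$feature[report$retained], report = report)
}

#' Train-set standardization
#'
#' `fit_standardizer()` learns per-feature means and sample standard
#' deviations (n-1 denominator) on the training table;
#' `standardize()` applies those training parameters to any table, so
#' test-set features are centered and scaled with the train statistics.
#'
#' @param train Feature table to learn parameters from; zero-variance
#'   features must have been removed first.
#' @return A `standardizer` object (tibble of `feature`, `mean`, `sd`).
#' @export
fit_standardizer <- function(train) {
  train <- validate_feature_table(train, require_label = "label" %in% names(train))
  feats <- feature_names(train)
  mu <- vapply(train[feats], mean, numeric(1))
  s <- vapply(train[feats], sd, numeric(1))
  if (any(s == 0)) {
    abort(sprintf("feature '%s' has zero train variance; run drop_zero_variance() first",
                  feats[which(s == 0)[1]]))
  }
  structure(tibble(feature = feats, mean = unname(mu), sd = unname(s)),
            class = c("standardizer", "tbl_df", "tbl", "data.frame"))
}

#' @rdname fit_standardizer
#' @param table Table to transform with the training parameters.
#' @param params A `standardizer` from [fit_standardizer()].
#' @export
standardize <- function(table, params) {
  stopifnot(inherits(params, "standardizer"))
  missing <- setdiff(params$feature, names(table))
  if (length(missing)) abort(sprintf("feature '%s' absent from table", missing[1]))
  out <- as_tibble(table)
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    out[[f]] <- (out[[f]] - params$mean[i]) / params$sd[i]
  }
  out
}

#' @rdname fit_standardizer
#' @export
unstandardize <- function(table, params) {
  stopifnot(inherits(params, "standardizer"))
  out <- as_tibble(table)
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    out[[f]] <- out[[f]] * params$sd[i] + params$mean[i]
  }
  out
}

#' Distribution-adaptive imputation of clinical covariates
#'
#' Continuous variables that pass a Shapiro-Wilk normality test (at
#' `alpha`) on their observed values are mean-imputed; continuous
#' variables failing it are median-imputed; categorical variables are
#' mode-imputed. Observed cells are never altered.
#'
#' @param table A clinical table (possibly with `NA` cells).
#' @param alpha Normality-test level (default 0.05).
#' @param max_missing Error if a variable exceeds this missing fraction.
#' @return The completed clinical table, plus an `imputation` attribute
#'   recording the method per variable.
#' @export
impute_clinical <- function(table, alpha = 0.05, max_missing = 0.5) {
  table <- validate_clinical_table(table)
  out <- as_tibble(table)
  vars <- setdiff(names(out), c("sample_id", "label"))
  types <- clinical_variables()
  log <- tibble(variable = character(), method = character(),
                n_imputed = integer())
  for (v in vars) {
    x <- out[[v]]
    miss <- is.na(x)
    if (!any(miss)) {
      log <- bind_rows(log, tibble(variable = v, method = "none", n_imputed = 0L))
      next
    }
    if (all(miss)) abort(sprintf("variable '%s' is entirely missing", v))
    if (mean(miss) > max_missing) {
      abort(sprintf("variable '%s' exceeds the %.0f%% missingness cap",
                    v, 100 * max_missing))
    }
    type <- types$type[match(v, types$variable)]
    if (is.na(type)) type <- if (is.numeric(x)) "continuous" else "categorical"
    obs <- x[!miss]
    if (type == "categorical" || !is.numeric(x)) {
      ux <- sort(unique(obs))
      fill <- ux[which.max(tabulate(match(obs, ux)))]
      method <- "mode"
    } else if (length(unique(obs)) > 2 &&
               shapiro.test(obs)$p.value >= alpha) {
      fill <- mean(obs); method <- "mean"
    } else {
      fill <- median(obs); method <- "median"
    }
    x[miss] <- fill
    out[[v]] <- x
    log <- bind_rows(log, tibble(variable = v, method = method,
                                 n_imputed = sum(miss)))
  }
  attr(out, "imputation") <- log
  out
}
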