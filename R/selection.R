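#' Configuration of the iterative robust feature selection
#'
#' Defaults mirror the published procedure: per iteration the derivation
#' cohort is split at seven train fractions (8:2 down to 5:5), each split
#' is filtered (zero variance, redundancy at |r| > 0.9, permutation
#' screen), a Lasso is fitted at the 10-fold-CV minimum-MSE penalty, and
#' the candidate is accepted when the train and test ROC curves do not
#' differ (DeLong p > `delong_alpha`) while the test-set Radiomics Score
#' separates the groups (permutation p < `rs_perm_alpha`). 1000 iterations
#' give 7000 candidate models; features selected more than `min_count`
#' times are the robust set.
#'
#' `delong_alpha` is a knob because the source procedure states both
#' p > 0.05 and p > 0.50 for this gate in different places; 0.05 is the
#' default.
#'
#' @param split_ratios Train fractions, applied in order each iteration.
#' @param n_iterations Number of iterations over the ratio list.
#' @param redundancy_r,redundancy_alpha Correlation threshold and test
#'   level of the redundancy filter.
#' @param screen_alpha Retention level of the per-feature permutation
#'   screen.
#' @param n_permutations Monte-Carlo permutations per permutation test.
#' @param delong_alpha,rs_perm_alpha Acceptance-gate levels.
#' @param min_count Selection-count threshold (strictly greater retained).
#' @param cv_folds Folds of the Lasso penalty cross-validation.
#' @param seed Master seed; every candidate derives its own substream.
#' @return A `selection_config` list.
#' @export
selection_config <- function(split_ratios = c(0.8, 0.75, 0.7, 0.65, 0.6, 0.55, 0.5),
                             n_iterations = 1000,
                             redundancy_r = 0.9, redundancy_alpha = 0.05,
                             screen_alpha = 0.05, n_permutations = 9999,
                             delong_alpha = 0.05, rs_perm_alpha = 0.05,
                             min_count = 100, cv_folds = 10, seed = 1L) {
  purrr::walk(split_ratios, assert_fraction, name = "split_ratios")
  if (n_iterations < 0) abort("n_iterations must be >= 0")
  if (n_iterations > 0 && min_count >= n_iterations * length(split_ratios)) {
    abort("min_count must be below n_iterations * length(split_ratios)")
  }
  structure(list(split_ratios = split_ratios, n_iterations = n_iterations,
                 redundancy_r = redundancy_r, redundancy_alpha = redundancy_alpha,
                 screen_alpha = screen_alpha, n_permutations = n_permutations,
                 delong_alpha = delong_alpha, rs_perm_alpha = rs_perm_alpha,
                 min_count = min_count, cv_folds = cv_folds, seed = seed),
            class = "selection_config")
}

#' Stratified train/test split
#'
#' Randomly partitions a cohort into train and test sets, stratified by
#' label: each label stratum contributes `round(fraction * n_stratum)`
#' samples to the train set.
#'
#' @param table Feature table.
#' @param train_fraction Train fraction in (0, 1).
#' @param seed RNG seed.
#' @return List of `train` and `test` feature tables.
#' @export
split_cohort <- function(table, train_fraction, seed = 1L) {
  table <- validate_feature_table(table)
  assert_fraction(train_fraction, "train_fraction")
  assert_binary_labels(table$label)
  idx_train <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(l) {
      stratum <- which(table$label == l)
      k <- round(train_fraction * length(stratum))
      if (k == 0 || k == length(stratum)) {
        abort(sprintf("label-%d stratum would be empty in train or test", l))
      }
      sample(stratum, k)
    }))
  })
  list(train = table[sort(idx_train), ],
       test = table[-sort(idx_train), ])
}

#' Zero-variance filter
#'
#' Removes features whose training variance is exactly zero (constant
#' columns); near-constant features are retained.
#'
#' @param train Feature table.
#' @return List with `retained` and `dropped` feature names.
#' @export
drop_zero_variance <- function(train) {
  train <- validate_feature_table(train, require_label = "label" %in% names(train))
  feats <- feature_names(train)
  v <- vapply(train[feats], var, numeric(1))
  if (all(v == 0)) abort("all features have zero variance")
  list(retained = feats[v > 0], dropped = feats[v == 0])
}

# Correlation p-value from the t reference (used for both Pearson r and
# Spearman rho; an approximation for the latter).
cor_p_value <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), n - 2)
}

#' Normality-adaptive redundancy filter
#'
#' Scans feature pairs in column order; a pair is redundant when its
#' correlation exceeds `r_threshold` in absolute value with a correlation
#' test p below `alpha`. Pearson correlation is used when both features
#' pass a Shapiro-Wilk normality check, Spearman otherwise. Of each
#' redundant pair exactly one member is removed (greedy): the member with
#' the larger group-separation permutation p is dropped, remaining ties
#' broken lexicographically.
#'
#' @param train Feature table (standardized training split).
#' @param r_threshold Absolute correlation threshold (default 0.9).
#' @param alpha Correlation-test level.
#' @param screen_p Optional named vector of per-feature permutation-screen
#'   p-values used for the tie rule; computed on demand when `NULL`.
#' @param n_permutations,seed Used only when `screen_p` is `NULL`.
#' @return List with `retained` names and `removed` log tibble.
#' @export
redundancy_filter <- function(train, r_threshold = 0.9, alpha = 0.05,
                              screen_p = NULL, n_permutations = 999,
                              seed = 1L) {
  train <- validate_feature_table(train)
  feats <- feature_names(train)
  if (length(feats) < 2) {
    return(list(retained = feats,
                removed = tibble(kept = character(), removed = character(),
                                 r = numeric(), p_value = numeric(),
                                 method = character())))
  }
  X <- feature_matrix(train)
  n <- nrow(X)
  normal <- vapply(feats, function(f) {
    x <- X[, f]
    length(unique(x)) > 2 && shapiro.test(x)$p.value >= 0.05
  }, logical(1))
  pear <- suppressWarnings(cor(X, method = "pearson"))
  spear <- suppressWarnings(cor(X, method = "spearman"))
  if (is.null(screen_p)) {
    sp <- permutation_screen(train, alpha = 1, n_permutations = n_permutations,
                             seed = seed)
    screen_p <- setNames(sp$p_value, sp$feature)
  }
  removed <- logical(length(feats))
  log <- list()
  for (i in seq_along(feats)[-length(feats)]) {
    if (removed[i]) next
    for (j in seq(i + 1, length(feats))) {
      if (removed[i]) break
      if (removed[j]) next
      use_pearson <- normal[i] && normal[j]
      r <- if (use_pearson) pear[i, j] else spear[i, j]
      if (is.na(r) || abs(r) <= r_threshold) next
      p <- cor_p_value(r, n)
      if (p >= alpha) next
      pi <- screen_p[feats[i]]; pj <- screen_p[feats[j]]
      drop_j <- pj > pi || (pj == pi && feats[j] > feats[i])
      drop_idx <- if (drop_j) j else i
      keep_idx <- if (drop_j) i else j
      removed[drop_idx] <- TRUE
      log[[length(log) + 1]] <- tibble(
        kept = feats[keep_idx], removed = feats[drop_idx], r = r, p_value = p,
        method = if (use_pearson) "pearson" else "spearman")
    }
  }
  list(retained = feats[!removed],
       removed = if (length(log)) bind_rows(log) else
         tibble(kept = character(), removed = character(), r = numeric(),
                p_value = numeric(), method = character()))
}

#' Per-feature permutation screen
#'
#' Monte-Carlo two-sample permutation test (statistic: absolute group mean
#' difference, add-one correction) for every feature, with one shared set
#' of label permutations. Features with p >= `alpha` are marked for
#' removal.
#'
#' @param train Feature table with both labels present.
#' @param alpha Retention level.
#' @param n_permutations Number of permutations `B`.
#' @param seed RNG seed.
#' @return Tibble: `feature`, `p_value` (in `[1/(B+1), 1]`), `retained`.
#' @export
permutation_screen <- function(train, alpha = 0.05, n_permutations = 9999,
                               seed = 1L) {
  train <- validate_feature_table(train)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  labels <- assert_binary_labels(train$label)
  X <- feature_matrix(train)
  n <- nrow(X); m <- sum(labels == 1)
  csum <- colSums(X)
  obs <- abs(colMeans(X[labels == 1, , drop = FALSE]) -
               colMeans(X[labels == 0, , drop = FALSE]))
  B <- n_permutations
  perm_stats <- with_seed(seed, {
    idx <- vapply(seq_len(B), function(b) sample.int(n, m), integer(m))
    P <- matrix(0, B, n)
    P[cbind(rep(seq_len(B), each = m), as.vector(idx))] <- 1
    s1 <- P %*% X
    abs(s1 / m - sweep(-s1, 2, csum, `+`) / (n - m))
  })
  exceed <- colSums(sweep(perm_stats, 2, obs - 1e-12, `>=`))
  p <- (1 + exceed) / (B + 1)
  fast_tibble(feature = colnames(X), p_value = unname(p),
              retained = unname(p) < alpha)
}

#' Cross-validated Lasso scorer
#'
#' Fits a Lasso-penalized linear regression of the 0/1 label on the
#' (standardized) features over a logarithmic penalty grid — 100 points
#' from the smallest penalty nulling every coefficient down four decades —
#' and keeps the penalty minimizing the `cv_folds`-fold cross-validated
#' mean squared error. The resulting Radiomics Score is
#' `RS = sum(feature * coefficient) + intercept`.
#'
#' @param train Standardized feature table.
#' @param cv_folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param alpha Elastic-net mixing (1 = Lasso, 0 = ridge).
#' @param lambda Optional penalty grid override.
#' @return A `linear_scorer`: nonzero-coefficient features, coefficients,
#'   intercept, penalty, CV curve.
#' @export
fit_lasso_cv <- function(train, cv_folds = 10, seed = 1L, alpha = 1,
                         lambda = NULL) {
  train <- validate_feature_table(train)
  X <- feature_matrix(train)
  y <- as.numeric(train$label)
  n <- nrow(X)
  if (n < cv_folds) abort("fewer samples than folds")
  if (ncol(X) < 2) abort("need at least 2 features")
  if (is.null(lambda)) {
    if (alpha > 0) {
      lam_max <- max(abs(crossprod(X, y - mean(y)))) / (n * alpha)
    } else {
      # ridge shrinks smoothly; anchor the grid at the Lasso-scale maximum
      # inflated two decades
      lam_max <- max(abs(crossprod(X, y - mean(y)))) / n * 100
    }
    lambda <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = 100))
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cvm <- numeric(length(lambda))
  for (f in seq_len(cv_folds)) {
    tr <- foldid != f
    g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                        alpha = alpha, lambda = lambda, standardize = FALSE,
                        type.gaussian = "covariance")
    pr <- X[!tr, , drop = FALSE] %*% as.matrix(g$beta) +
      matrix(g$a0, sum(!tr), length(g$a0), byrow = TRUE)
    if (ncol(pr) < length(lambda)) {  # glmnet may stop the path early
      pr <- cbind(pr, matrix(pr[, ncol(pr)], nrow(pr), length(lambda) - ncol(pr)))
    }
    cvm <- cvm + colSums((pr - y[!tr])^2)
  }
  cvm <- unname(cvm) / n
  best <- which.min(cvm)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        type.gaussian = "covariance")
  cf <- if (best <= length(fit$lambda)) {
    c(fit$a0[[best]], as.numeric(fit$beta[, best]))
  } else {
    as.numeric(coef(fit, s = lambda[best]))
  }
  names(cf) <- c("(Intercept)", colnames(X))
  nz <- cf[-1][cf[-1] != 0]
  new_linear_scorer(
    family = if (alpha == 1) "lasso" else if (alpha == 0) "ridge" else "enet",
    coefficients = fast_tibble(term = names(nz), estimate = unname(nz)),
    intercept = unname(cf[1]),
    lambda = lambda[best],
    cv = fast_tibble(lambda = lambda, cvm = cvm))
}

new_linear_scorer <- function(family, coefficients, intercept, lambda = NA_real_,
                              cv = NULL, standardizer = NULL) {
  structure(list(family = family, coefficients = coefficients,
                 intercept = intercept, lambda = lambda, cv = cv,
                 standardizer = standardizer),
            class = "linear_scorer")
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat(sprintf("<linear_scorer: %s, %d feature(s), intercept %.4g>\n",
              x$family, nrow(x$coefficients), x$intercept))
  print(x$coefficients, n = 10)
  invisible(x)
}

#' Radiomics Score of each sample
#'
#' `RS_i = sum_j value_ij * coefficient_j + intercept`. The table must
#' already be standardized with the scorer's training parameters (or pass
#' `standardized = FALSE` to have the scorer's stored parameters applied).
#'
#' @param scorer A `linear_scorer`.
#' @param table Feature table containing every scorer feature.
#' @param standardized Is `table` already on the training z-scale?
#' @return Numeric RS vector named by `sample_id`.
#' @export
compute_rs <- function(scorer, table, standardized = TRUE) {
  stopifnot(inherits(scorer, "linear_scorer"))
  missing <- setdiff(scorer$coefficients$term, names(table))
  if (length(missing)) {
    abort(sprintf("table is missing scorer feature '%s'", missing[1]))
  }
  if (!standardized) {
    if (is.null(scorer$standardizer)) abort("scorer carries no standardizer")
    table <- standardize(table, scorer$standardizer)
  }
  if (nrow(scorer$coefficients) == 0) {
    return(setNames(rep(scorer$intercept, nrow(table)), table$sample_id))
  }
  X <- as.matrix(table[scorer$coefficients$term])
  rs <- drop(X %*% scorer$coefficients$estimate) + scorer$intercept
  setNames(rs, table$sample_id)
}

#' Dual acceptance gate of one candidate model
#'
#' Scores the (standardized) train and test splits, compares their ROC
#' curves with the unpaired DeLong test and tests the Radiomics Score
#' group separation on each split with permutation tests. The candidate
#' is accepted iff DeLong p > `delong_alpha` (generalization holds) and
#' the test-set permutation p < `rs_perm_alpha` (separation holds).
#' Degenerate scorers (no selected features, constant RS) are
#' auto-rejected with a reason.
#'
#' @param scorer A `linear_scorer` from [fit_lasso_cv()].
#' @param train,test Standardized splits (test on the train parameters).
#' @param config A [selection_config()].
#' @param seed RNG seed for the permutation tests.
#' @param iteration,ratio Bookkeeping fields for the record.
#' @return One-row tibble (an iteration record): `iteration`, `ratio`,
#'   `n_selected`, `features` (list-column), `delong_p`,
#'   `train_rs_perm_p`, `test_rs_perm_p`, `accepted`, `reason`.
#' @export
accept_candidate <- function(scorer, train, test, config = selection_config(),
                             seed = 1L, iteration = NA_integer_,
                             ratio = NA_real_) {
  rec <- function(feats, dp = NA_real_, trp = NA_real_, tep = NA_real_,
                  acc = FALSE, reason = NA_character_) {
    fast_tibble(iteration = iteration, ratio = ratio,
                n_selected = length(feats), features = list(feats),
                delong_p = dp, train_rs_perm_p = trp, test_rs_perm_p = tep,
                accepted = acc, reason = reason)
  }
  feats <- scorer$coefficients$term
  if (length(feats) == 0) return(rec(character(), reason = "no selected features"))
  rs_train <- compute_rs(scorer, train)
  rs_test <- compute_rs(scorer, test)
  if (var(rs_train) == 0 || var(rs_test) == 0) {
    return(rec(feats, reason = "degenerate (constant) RS"))
  }
  seeds <- derive_seeds(seed, 2)
  dl <- delong_compare(rs_train, train$label, rs_test, test$label,
                       paired = FALSE)
  p_tr <- permutation_test_scores(rs_train, train$label,
                                  config$n_permutations, seeds[1])
  p_te <- permutation_test_scores(rs_test, test$label,
                                  config$n_permutations, seeds[2])
  rec(feats, dl$p_value, p_tr, p_te,
      acc = dl$p_value > config$delong_alpha && p_te < config$rs_perm_alpha)
}

#' Run the full iteration loop
#'
#' For every iteration and split ratio: split the cohort (stratified),
#' drop zero-variance features, standardize on the train split, apply the
#' redundancy filter and the permutation screen, fit the cross-validated
#' Lasso, and evaluate the dual acceptance gate. Accepted candidates
#' increment the selection count of each feature they carry with a
#' nonzero coefficient. Stage failures are logged per candidate and never
#' abort the loop.
#'
#' @param table Feature table (after ICC filtering).
#' @param config A [selection_config()].
#' @param progress Print a line every 500 candidates.
#' @return A `selection_result`: `counts` tibble, `records` tibble of all
#'   candidates, `n_candidates`, and the config.
#' @export
run_iterations <- function(table, config = selection_config(),
                           progress = FALSE) {
  table <- validate_feature_table(table)
  feats_all <- feature_names(table)
  n_ratio <- length(config$split_ratios)
  n_cand <- config$n_iterations * n_ratio
  counts <- setNames(rep(0L, length(feats_all)), feats_all)
  records <- vector("list", n_cand)
  if (n_cand > 0) {
    cand_seeds <- derive_seeds(config$seed, n_cand)
    k <- 0L
    for (it in seq_len(config$n_iterations)) {
      for (ri in seq_len(n_ratio)) {
        k <- k + 1L
        ratio <- config$split_ratios[ri]
        seeds <- derive_seeds(cand_seeds[k], 4)
        rec <- tryCatch(
          run_one_candidate(table, ratio, config, seeds, it),
          error = function(e) {
            tibble(iteration = it, ratio = ratio, n_selected = 0L,
                   features = list(character()), delong_p = NA_real_,
                   train_rs_perm_p = NA_real_, test_rs_perm_p = NA_real_,
                   accepted = FALSE, reason = conditionMessage(e))
          })
        records[[k]] <- rec
        if (rec$accepted) {
          sel <- rec$features[[1]]
          counts[sel] <- counts[sel] + 1L
        }
        if (progress && k %% 500 == 0) {
          inform(sprintf("candidate %d / %d", k, n_cand))
        }
      }
    }
  }
  structure(list(
    counts = tibble(feature = names(counts), count = unname(counts)),
    records = if (n_cand > 0) bind_rows(records) else
      tibble(iteration = integer(), ratio = numeric(), n_selected = integer(),
             features = list(), delong_p = numeric(),
             train_rs_perm_p = numeric(), test_rs_perm_p = numeric(),
             accepted = logical(), reason = character()),
    n_candidates = n_cand, config = config),
    class = "selection_result")
}

run_one_candidate <- function(table, ratio, config, seeds, iteration) {
  sp <- split_cohort(table, ratio, seeds[1])
  zv <- drop_zero_variance(sp$train)
  train <- sp$train[c("sample_id", "label", zv$retained)]
  test <- sp$test[c("sample_id", "label", zv$retained)]
  std <- fit_standardizer(train)
  train <- standardize(train, std)
  test <- standardize(test, std)
  screen <- permutation_screen(train, alpha = config$screen_alpha,
                               n_permutations = config$n_permutations,
                               seed = seeds[2])
  screen_p <- setNames(screen$p_value, screen$feature)
  red <- redundancy_filter(train, config$redundancy_r, config$redundancy_alpha,
                           screen_p = screen_p)
  keep <- red$retained[screen_p[red$retained] < config$screen_alpha]
  if (length(keep) < 2) {
    return(tibble(iteration = iteration, ratio = ratio, n_selected = 0L,
                  features = list(character()), delong_p = NA_real_,
                  train_rs_perm_p = NA_real_, test_rs_perm_p = NA_real_,
                  accepted = FALSE,
                  reason = sprintf("only %d feature(s) survived screening",
                                   length(keep))))
  }
  scorer <- fit_lasso_cv(train[c("sample_id", "label", keep)],
                         cv_folds = config$cv_folds, seed = seeds[3])
  scorer$standardizer <- std
  accept_candidate(scorer, train[c("sample_id", "label", keep)],
                   test[c("sample_id", "label", keep)],
                   config, seed = seeds[4], iteration = iteration,
                   ratio = ratio)
}

#' @export
print.selection_result <- function(x, ...) {
  acc <- sum(x$records$accepted)
  cat(sprintf("<selection_result: %d candidates, %d accepted (%.1f%%)>\n",
              x$n_candidates, acc,
              if (x$n_candidates) 100 * acc / x$n_candidates else 0))
  print(head(arrange(x$counts, desc(.data$count)), 10))
  invisible(x)
}

#' Robust feature set from the selection counts
#'
#' Features selected strictly more than `min_count` times across accepted
#' candidate models, sorted by descending count then name.
#'
#' @param result A `selection_result`.
#' @param min_count Count threshold (strict inequality).
#' @return Character vector of feature names.
#' @export
select_robust_features <- function(result, min_count = NULL) {
  stopifnot(inherits(result, "selection_result"))
  min_count <- min_count %||% result$config$min_count
  hits <- result$counts |>
    filter(.data$count > min_count) |>
    arrange(desc(.data$count), .data$feature)
  hits$feature
}
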