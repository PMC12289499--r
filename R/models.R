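#' Final modeling split
#'
#' The robust-feature modeling stage re-splits the derivation cohort at
#' 6.5:3.5 (stratified), e.g. 78/42 with 39/39 labels in train for the
#' standard 120-sample cohort.
#'
#' @inheritParams split_cohort
#' @export
final_split <- function(table, seed = 1L) {
  split_cohort(table, 0.65, seed)
}

#' Train a linear Radiomics scorer
#'
#' Four score-producing families over the robust features: `ridge` and
#' `lasso` (penalty tuned by 10-fold CV at minimum MSE), `logistic`
#' (unpenalized ML fit; RS = linear predictor) and `lda` (Fisher
#' discriminant; RS = posterior log-odds, linear in the features). All
#' return a [linear_scorer][fit_lasso_cv] so the downstream Youden /
#' permutation / DeLong machinery applies uniformly.
#'
#' @param train Standardized feature table restricted to robust features.
#' @param family One of `"ridge"`, `"lasso"`, `"logistic"`, `"lda"`.
#' @param cv_folds,seed Passed to the penalty cross-validation.
#' @return A `linear_scorer`.
#' @export
train_linear_scorer <- function(train, family = c("ridge", "lasso", "logistic", "lda"),
                                cv_folds = 10, seed = 1L) {
  family <- match.arg(family)
  train <- validate_feature_table(train)
  feats <- feature_names(train)
  X <- feature_matrix(train)
  y <- train$label
  if (family %in% c("ridge", "lasso")) {
    sc <- fit_lasso_cv(train, cv_folds = cv_folds, seed = seed,
                       alpha = if (family == "lasso") 1 else 0)
    sc$family <- family
    return(sc)
  }
  if (family == "logistic") {
    df <- data.frame(y = y, X, check.names = FALSE)
    fit <- glm(y ~ ., data = df, family = binomial())
    cf <- coef(fit)
    return(new_linear_scorer(
      family = "logistic",
      coefficients = tibble(term = feats, estimate = unname(cf[-1])),
      intercept = unname(cf[1])))
  }
  # LDA: posterior log-odds are linear with w = S^-1 (mu1 - mu0); the fit
  # itself goes through MASS::lda and the direction is cross-checked there
  ld <- MASS::lda(X, grouping = factor(y))
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  S <- ((n0 - 1) * cov(X[y == 0, , drop = FALSE]) +
          (n1 - 1) * cov(X[y == 1, , drop = FALSE])) / (n0 + n1 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    abort("singular within-class covariance; LDA is not identifiable here")
  })
  b <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  sc <- new_linear_scorer(
    family = "lda",
    coefficients = tibble(term = feats, estimate = unname(w)),
    intercept = b)
  sc$lda_fit <- ld
  sc
}

#' Tune a k-nearest-neighbor classifier
#'
#' Sweeps k over `k_range` (default 1..50), scoring each k by
#' `cv_folds`-fold cross-validated accuracy on the training set; ties are
#' broken toward the smaller k. Distances are Euclidean on the
#' standardized features. Prediction returns neighbor vote fractions as
#' class probabilities.
#'
#' @param train Standardized feature table.
#' @param k_range Candidate neighborhood sizes.
#' @param cv_folds,seed CV fold count and RNG seed.
#' @return A `knn_model`: chosen `k`, CV accuracy curve, training data.
#' @export
tune_knn <- function(train, k_range = 1:50, cv_folds = 10, seed = 1L) {
  train <- validate_feature_table(train)
  X <- feature_matrix(train)
  y <- factor(train$label, levels = c(0, 1))
  n <- nrow(X)
  seeds <- derive_seeds(seed, 2)
  foldid <- with_seed(seeds[1], sample(rep_len(seq_len(cv_folds), n)))
  min_fold_train <- min(vapply(seq_len(cv_folds),
                               function(f) sum(foldid != f), integer(1)))
  usable <- k_range[k_range <= min_fold_train]
  skipped <- setdiff(k_range, usable)
  if (length(skipped)) {
    inform(sprintf("skipping %d grid point(s) with k exceeding the fold train size",
                   length(skipped)))
  }
  acc <- with_seed(seeds[2], vapply(usable, function(k) {
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      pred <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                         y[tr], k = k)
      hits <- hits + sum(pred == y[!tr])
    }
    hits / n
  }, numeric(1)))
  k_star <- usable[which.max(acc)]   # which.max -> first max -> smallest k
  structure(list(k = k_star, cv = tibble(k = usable, accuracy = acc),
                 X = X, y = y, seed = seeds[2]),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model: k = %d, CV accuracy %.3f>\n", x$k,
              x$cv$accuracy[x$cv$k == x$k]))
  invisible(x)
}

#' Tune a support-vector machine over kernel functions
#'
#' Splits the cohort three ways (stratified; default 65/17.5/17.5 train /
#' validation / test), trains one SVM per candidate kernel on the train
#' part and picks the kernel maximizing validation accuracy (ties broken
#' by kernel order). Unavailable kernels are logged and skipped, never
#' silently substituted. Class probabilities come from a monotone
#' logistic (Platt) calibration of the decision values, fitted on the
#' training part.
#'
#' @param table Standardized feature table (whole derivation cohort).
#' @param kernels Candidate kernlab kernel names.
#' @param split Three fractions summing to 1.
#' @param cost SVM cost parameter (fixed, conventional default 1).
#' @param seed RNG seed.
#' @return An `svm_model`: chosen kernel, fit, calibration, the three
#'   splits and the per-kernel validation accuracies.
#' @export
tune_svm <- function(table, kernels = c("rbfdot", "polydot", "tanhdot",
                                        "vanilladot", "laplacedot",
                                        "besseldot", "anovadot"),
                     split = c(0.65, 0.175, 0.175), cost = 1, seed = 1L) {
  table <- validate_feature_table(table)
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8)
  seeds <- derive_seeds(seed, 3)
  s1 <- split_cohort(table, split[1], seeds[1])
  s2 <- split_cohort(s1$test, split[2] / (split[2] + split[3]), seeds[2])
  train <- s1$train; valid <- s2$train; test <- s2$test
  Xtr <- feature_matrix(train); ytr <- factor(train$label, levels = c(0, 1))
  Xva <- feature_matrix(valid)
  fits <- list(); accs <- rep(NA_real_, length(kernels))
  for (i in seq_along(kernels)) {
    kern <- kernels[i]
    fit <- tryCatch(
      with_seed(seeds[3], kernlab::ksvm(
        Xtr, ytr, kernel = kern, C = cost,
        kpar = if (kern %in% c("rbfdot", "laplacedot")) "automatic" else list(),
        scaled = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      inform(sprintf("kernel '%s' unavailable; skipped", kern))
      next
    }
    pred <- predict(fit, Xva)
    accs[i] <- mean(pred == factor(valid$label, levels = c(0, 1)))
    fits[[kern]] <- fit
  }
  if (!length(fits)) abort("no SVM kernel could be fitted")
  best <- which.max(accs)            # first max respects kernel order
  kern <- kernels[best]
  fit <- fits[[kern]]
  dec_tr <- as.numeric(predict(fit, Xtr, type = "decision"))
  calib <- suppressWarnings(glm(I(as.integer(ytr) - 1L) ~ dec_tr,
                                family = binomial()))
  structure(list(kernel = kern, fit = fit,
                 calibration = unname(coef(calib)),
                 validation = tibble(kernel = kernels, accuracy = accs),
                 train = train, valid = valid, test = test),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model: kernel '%s', validation accuracy %.3f>\n",
              x$kernel, max(x$validation$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Score samples with any fitted radiomic model
#'
#' Uniform scoring interface: linear scorers return the Radiomics Score,
#' KNN models the neighbor vote fraction for class 1, SVM models the
#' Platt-calibrated probability.
#'
#' @param model A `linear_scorer`, `knn_model` or `svm_model`.
#' @param table Standardized feature table.
#' @return Numeric score vector named by sample id.
#' @export
score_samples <- function(model, table) {
  if (inherits(model, "linear_scorer")) return(compute_rs(model, table))
  X <- as.matrix(table[colnames(if (inherits(model, "knn_model")) model$X
                                else feature_matrix(model$train))])
  if (inherits(model, "knn_model")) {
    pred <- with_seed(model$seed,
                      class::knn(model$X, X, model$y, k = model$k, prob = TRUE))
    win <- attr(pred, "prob")
    p1 <- ifelse(pred == "1", win, 1 - win)
    return(setNames(p1, table$sample_id))
  }
  if (inherits(model, "svm_model")) {
    dec <- as.numeric(predict(model$fit, X, type = "decision"))
    p1 <- stats::plogis(model$calibration[1] + model$calibration[2] * dec)
    return(setNames(p1, table$sample_id))
  }
  abort("unknown model type")
}

#' Assess a fitted scorer on train and test splits
#'
#' Computes scores on both splits, fixes the operating cutoff by the
#' Youden index on the train scores (reapplied unchanged to test), fills
#' both performance reports, and evaluates the generalization /
#' separation gates: unpaired DeLong p between the train and test ROC
#' curves and permutation p of the score between the label groups on each
#' split. The model is a success iff both permutation p-values are below
#' 0.05.
#'
#' @param model A fitted model (see [score_samples()]).
#' @param train,test Standardized splits.
#' @param n_permutations,seed Permutation-test settings.
#' @return A `model_assessment`.
#' @export
assess_scorer <- function(model, train, test, n_permutations = 9999,
                          seed = 1L) {
  s_tr <- score_samples(model, train)
  s_te <- score_samples(model, test)
  family <- if (inherits(model, "linear_scorer")) model$family else
    if (inherits(model, "knn_model")) "knn" else "svm"
  if (var(s_tr) == 0 || var(s_te) == 0) {
    return(structure(list(model_family = family, failure = "degenerate scores",
                          success = FALSE),
                     class = "model_assessment"))
  }
  seeds <- derive_seeds(seed, 2)
  yc <- youden_cutoff(s_tr, train$label)
  rep_tr <- performance_report(s_tr, train$label, yc$cutoff)
  rep_te <- performance_report(s_te, test$label, yc$cutoff)
  dl <- delong_compare(s_tr, train$label, s_te, test$label, paired = FALSE)
  p_tr <- permutation_test_scores(s_tr, train$label, n_permutations, seeds[1])
  p_te <- permutation_test_scores(s_te, test$label, n_permutations, seeds[2])
  structure(list(model_family = family, model = model,
                 cutoff = yc$cutoff, youden = yc,
                 train_report = rep_tr, test_report = rep_te,
                 delong_p = dl$p_value,
                 train_rs_perm_p = p_tr, test_rs_perm_p = p_te,
                 success = p_tr < 0.05 && p_te < 0.05,
                 failure = NA_character_),
            class = "model_assessment")
}

#' @export
print.model_assessment <- function(x, ...) {
  if (!is.na(x$failure %||% NA)) {
    cat(sprintf("<model_assessment: %s FAILED (%s)>\n", x$model_family, x$failure))
    return(invisible(x))
  }
  cat(sprintf("<model_assessment: %s | train AUC %.3f, test AUC %.3f | DeLong p %.3f | perm p %.3g / %.3g | %s>\n",
              x$model_family, x$train_report$auc, x$test_report$auc,
              x$delong_p, x$train_rs_perm_p, x$test_rs_perm_p,
              if (x$success) "success" else "failure"))
  invisible(x)
}

#' Choose the best scorer among assessed model families
#'
#' Among successful models: maximum test AUC, ties broken by the smaller
#' train/test AUC gap, then by the larger train AUC.
#'
#' @param assessments List of `model_assessment` objects.
#' @return List with `outcome` (`"ok"` or `"no successful model"`) and
#'   `chosen` (the winning assessment, or `NULL`).
#' @export
select_best_scorer <- function(assessments) {
  stopifnot(length(assessments) >= 1)
  ok <- purrr::keep(assessments, ~ isTRUE(.x$success))
  if (!length(ok)) return(list(outcome = "no successful model", chosen = NULL))
  key <- purrr::map_dfr(ok, function(a) {
    tibble(test_auc = a$test_report$auc,
           gap = abs(a$train_report$auc - a$test_report$auc),
           train_auc = a$train_report$auc)
  })
  ord <- order(-key$test_auc, key$gap, -key$train_auc)
  list(outcome = "ok", chosen = ok[[ord[1]]])
}
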