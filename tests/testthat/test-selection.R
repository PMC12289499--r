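test_that("stratified splits have the published sizes", {
  tab <- simulate_feature_table(sim_config(seed = 1), "derivation")$table
  sp <- split_cohort(tab, 0.8, seed = 2)
  expect_equal(nrow(sp$train), 96)
  expect_equal(nrow(sp$test), 24)
  expect_equal(sum(sp$train$label == 1), 48)
  expect_equal(sum(sp$test$label == 1), 12)
  sp65 <- split_cohort(tab, 0.65, seed = 2)
  expect_equal(nrow(sp65$train), 78)
  expect_equal(nrow(sp65$test), 42)
  # partition is disjoint and exhaustive
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), tab$sample_id)
  # determinism
  expect_identical(split_cohort(tab, 0.7, seed = 5),
                   split_cohort(tab, 0.7, seed = 5))
  expect_false(identical(split_cohort(tab, 0.7, seed = 5)$train$sample_id,
                         split_cohort(tab, 0.7, seed = 6)$train$sample_id))
  expect_error(split_cohort(tab[c(1:3, 61), ], 0.9), "empty")
})

test_that("zero-variance dropping uses the exact-zero rule", {
  tab <- tiny_table(n = 30, p = 3)
  tab$glcm_f02 <- 7                       # constant
  tab$glcm_f03 <- tab$glcm_f03 * 1e-9     # near-constant but nonzero
  zv <- drop_zero_variance(tab)
  expect_equal(zv$dropped, "glcm_f02")
  expect_true("glcm_f03" %in% zv$retained)
  # generator truth: exactly the planted constants are dropped
  out <- simulate_feature_table(sim_config(n_zero_variance = 4, seed = 2),
                                "derivation")
  zv2 <- drop_zero_variance(out$table)
  expect_setequal(zv2$dropped, out$truth$zero_variance)
})

test_that("redundancy filter removes exactly one member per duplicate pair", {
  tab <- tiny_table(n = 50, p = 3, seed = 4)
  tab$glcm_f02 <- tab$glcm_f01            # exact duplicate
  res <- redundancy_filter(tab, seed = 1)
  expect_length(intersect(c("glcm_f01", "glcm_f02"), res$retained), 1)
  expect_true("glcm_f03" %in% res$retained)
  # orthogonal features all retained
  tab2 <- tiny_table(n = 100, p = 6, seed = 5)
  res2 <- redundancy_filter(tab2, seed = 1)
  expect_setequal(res2$retained, feature_names(tab2))
  # planted r = 0.95 removed, r = 0.85 retained
  withr::with_seed(6, {
    x <- rnorm(100)
    strong <- 0.95 * x + sqrt(1 - 0.95^2) * rnorm(100)
    weak <- 0.85 * x + sqrt(1 - 0.85^2) * rnorm(100)
  })
  tab3 <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                         label = rep(c(0L, 1L), 50),
                         glcm_f01 = x, glcm_f02 = strong, glcm_f03 = weak)
  res3 <- redundancy_filter(tab3, seed = 1)
  expect_length(intersect(c("glcm_f01", "glcm_f02"), res3$retained), 1)
  expect_true("glcm_f03" %in% res3$retained)
  # no surviving pair exceeds the threshold
  surv <- as.matrix(tab3[res3$retained])
  cc <- cor(surv)
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.9))
})

test_that("permutation screen is calibrated and matches enumeration", {
  # type-I calibration on a fully null table
  tab <- tiny_table(n = 60, p = 400, seed = 7)
  sc <- permutation_screen(tab, alpha = 0.05, n_permutations = 499, seed = 3)
  frac <- mean(sc$retained)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # p-values live in [1/(B+1), 1]
  expect_gte(min(sc$p_value), 1 / 500)
  expect_lte(max(sc$p_value), 1)
  # 3-vs-3 instance against the exhaustive oracle
  v <- c(0.4, 2.2, 1.0, 3.1, 2.8, 4.6)
  tab6 <- tibble::tibble(sample_id = as.character(1:6),
                         label = c(0L, 0L, 0L, 1L, 1L, 1L), glcm_f01 = v)
  sc6 <- permutation_screen(tab6, n_permutations = 19999, seed = 5)
  expect_equal(sc6$p_value, perm_p_exhaustive_3v3(v), tolerance = 0.02)
  # a feature identical across groups is removed
  tabid <- tibble::tibble(sample_id = as.character(1:20),
                          label = rep(c(0L, 1L), 10),
                          glcm_f01 = rep(1:10, each = 2))
  scid <- permutation_screen(tabid, n_permutations = 499, seed = 2)
  expect_false(scid$retained)
  expect_gt(scid$p_value, 0.5)
})

test_that("the CV Lasso equals the cv.glmnet oracle and shrinks fully", {
  tab <- tiny_table(n = 60, p = 8, d = 1.5, seed = 2)
  sc <- fit_lasso_cv(tab, cv_folds = 5, seed = 9)
  X <- as.matrix(tab[feature_names(tab)])
  foldid <- withr::with_seed(9L, sample(rep_len(1:5, 60)))
  cvfit <- glmnet::cv.glmnet(X, tab$label, family = "gaussian",
                             lambda = sc$cv$lambda, foldid = foldid,
                             standardize = FALSE)
  expect_equal(sc$lambda, cvfit$lambda.min)
  expect_equal(sc$cv$cvm, as.numeric(cvfit$cvm), tolerance = 1e-10)
  cf <- as.numeric(coef(cvfit, s = "lambda.min"))
  expect_equal(sc$intercept, cf[1], tolerance = 1e-10)
  # penalty at the grid maximum nulls every coefficient
  sc_max <- fit_lasso_cv(tab, cv_folds = 5, seed = 9, lambda = c(50, 49))
  expect_equal(nrow(sc_max$coefficients), 0)
  expect_equal(sc_max$intercept, mean(tab$label))
  # a strongly informative feature gets a nonzero coefficient
  tab2 <- tiny_table(n = 120, p = 10, d = 2, seed = 3)
  sc2 <- fit_lasso_cv(standardize(tab2, fit_standardizer(tab2)), seed = 4)
  expect_true("glcm_f01" %in% sc2$coefficients$term)
  expect_error(fit_lasso_cv(tab[1:4, ], cv_folds = 10), "fewer samples")
})

test_that("the Radiomics Score is the coefficient dot product plus intercept", {
  sc <- radscore:::new_linear_scorer(
    "lasso", tibble::tibble(term = c("glcm_f01", "glcm_f02"),
                            estimate = c(0.5, 0.2)), intercept = 0.1)
  tab <- tibble::tibble(sample_id = "a", glcm_f01 = 1, glcm_f02 = -1)
  expect_equal(unname(compute_rs(sc, tab)), 0.4)
  # 50 random scorers against a brute-force dot product
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- sample(2:6, 1); n <- sample(3:8, 1)
      feats <- paste0("glcm_f", sprintf("%02d", 1:p))
      co <- rnorm(p); ic <- rnorm(1)
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, feats))
      s <- radscore:::new_linear_scorer(
        "lasso", tibble::tibble(term = feats, estimate = co), intercept = ic)
      tabi <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                               tibble::as_tibble(as.data.frame(X)))
      manual <- as.numeric(X %*% co) + ic
      expect_equal(unname(compute_rs(s, tabi)), manual, tolerance = 1e-12)
    }
  })
  # missing feature errors by name
  expect_error(compute_rs(sc, tab[, 1:2]), "glcm_f02")
  # all-zero scorer returns the intercept
  sc0 <- radscore:::new_linear_scorer(
    "lasso", tibble::tibble(term = character(), estimate = numeric()),
    intercept = 0.7)
  expect_equal(unname(compute_rs(sc0, tab)), 0.7)
})

test_that("the acceptance gate implements the dual criterion", {
  cfg <- selection_config(n_permutations = 499, seed = 1)
  # strong planted signal is accepted in the large majority of seeded runs
  acc <- purrr::map_lgl(1:10, function(s) {
    tab <- tiny_table(n = 120, p = 6, d = 2, seed = s)
    sp <- split_cohort(tab, 0.7, seed = s)
    std <- fit_standardizer(sp$train)
    tr <- standardize(sp$train, std); te <- standardize(sp$test, std)
    scorer <- fit_lasso_cv(tr, seed = s)
    rec <- accept_candidate(scorer, tr, te, cfg, seed = s)
    rec$accepted
  })
  expect_gte(mean(acc), 0.8)
  # record invariant: accepted == (delong_p > alpha) & (test perm p < alpha)
  tab <- tiny_table(n = 80, p = 6, d = 1, seed = 3)
  sp <- split_cohort(tab, 0.7, seed = 3)
  std <- fit_standardizer(sp$train)
  tr <- standardize(sp$train, std); te <- standardize(sp$test, std)
  rec <- accept_candidate(fit_lasso_cv(tr, seed = 3), tr, te, cfg, seed = 4)
  expect_equal(rec$accepted,
               rec$delong_p > cfg$delong_alpha &
                 rec$test_rs_perm_p < cfg$rs_perm_alpha)
  # zero-feature scorer is auto-rejected with a reason
  sc0 <- radscore:::new_linear_scorer(
    "lasso", tibble::tibble(term = character(), estimate = numeric()), 0.3)
  rec0 <- accept_candidate(sc0, tr, te, cfg, seed = 1)
  expect_false(rec0$accepted)
  expect_match(rec0$reason, "no selected features")
  expect_equal(rec0$n_selected, 0L)
})

test_that("the iteration loop counts accepted features and is reproducible", {
  tab <- simulate_feature_table(
    sim_config(feature_class_counts = c(glcm = 12L), n_informative = 2,
               effect_sizes = 1.5, n_redundant_pairs = 1, n_zero_variance = 1,
               seed = 3), "derivation")$table
  cfg <- selection_config(n_iterations = 5, n_permutations = 99,
                          min_count = 3, seed = 21)
  res <- run_iterations(tab, cfg)
  expect_equal(res$n_candidates, 35)
  expect_equal(nrow(res$records), 35)
  # count conservation: totals match the accepted records
  manual <- table(unlist(res$records$features[res$records$accepted]))
  for (f in names(manual)) {
    expect_equal(res$counts$count[res$counts$feature == f],
                 as.integer(manual[[f]]))
  }
  expect_equal(sum(res$counts$count),
               sum(lengths(res$records$features[res$records$accepted])))
  # reruns are identical
  expect_identical(res$counts, run_iterations(tab, cfg)$counts)
  # zero iterations: empty log, zero counts
  res0 <- run_iterations(tab, selection_config(n_iterations = 0, seed = 1))
  expect_equal(res0$n_candidates, 0)
  expect_true(all(res0$counts$count == 0))
})

test_that("robust-feature selection is strict and monotone in the threshold", {
  res <- structure(list(
    counts = tibble::tibble(feature = c("A", "B", "C"),
                            count = c(150L, 100L, 99L)),
    records = tibble::tibble(accepted = logical()),
    n_candidates = 7000,
    config = selection_config(seed = 1)), class = "selection_result")
  expect_equal(select_robust_features(res, 100), "A")
  expect_equal(select_robust_features(res, 99), c("A", "B"))
  # raising min_count never grows the set
  sets <- purrr::map(c(0, 50, 99, 100, 150), ~ select_robust_features(res, .x))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # empty counts give an empty list
  res$counts <- tibble::tibble(feature = character(), count = integer())
  expect_length(select_robust_features(res, 0), 0)
})
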