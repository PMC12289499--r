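#' Run the full biomarker pipeline end to end
#'
#' Reproduces the complete study flow on synthetic or user data: ICC
#' filtering of two-rater replicates, iterative robust feature selection,
#' training of the six radiomic model families on the robust set,
#' best-scorer choice, staged clinical integration into the
#' Clinical-Radiomic Score, and evaluation (performance reports,
#' Hosmer-Lemeshow, calibration, decision curves, nomogram) on the
#' derivation and temporal validation cohorts. All artifacts are written
#' under `output_dir` when given.
#'
#' @param sim A [sim_config()] describing the synthetic cohorts, or
#'   `NULL` when `data` is supplied.
#' @param data Optional list with pre-loaded `derivation`, `validation`
#'   feature tables and `clinical_derivation`, `clinical_validation`
#'   tables (mutually exclusive with `sim`).
#' @param selection A [selection_config()]; its `seed` drives the whole
#'   run.
#' @param families Model families to train.
#' @param icc_threshold Reproducibility threshold.
#' @param clinical_alpha Screening / staged-selection level.
#' @param adjusted_cutoff Optional fixed Clin-Rad operating cutoff.
#' @param output_dir Optional directory for artifacts.
#' @return A `pipeline_run` list with every stage result and a manifest.
#' @export
run_pipeline <- function(sim = sim_config(),
                         data = NULL,
                         selection = selection_config(n_iterations = 200,
                                                      min_count = 20),
                         families = c("ridge", "lasso", "logistic", "lda",
                                      "knn", "svm"),
                         icc_threshold = 0.75,
                         clinical_alpha = 0.05,
                         adjusted_cutoff = NULL,
                         output_dir = NULL) {
  if (is.null(data) == is.null(sim)) {
    abort("supply exactly one of `sim` or `data`")
  }
  seeds <- derive_seeds(selection$seed, 8)
  if (!is.null(sim)) {
    der <- simulate_feature_table(sim, "derivation")
    val <- simulate_feature_table(sim, "validation")
    reps <- simulate_rater_replicates(der$table, sim$rater_noise_sd, seeds[1])
    data <- list(derivation = der$table, validation = val$table,
                 clinical_derivation = simulate_clinical_table(sim, "derivation"),
                 clinical_validation = simulate_clinical_table(sim, "validation"),
                 replicates = reps, truth = der$truth)
  }
  stages <- list()

  # 1. reproducibility filter
  if (!is.null(data$replicates)) {
    icc <- icc_filter(data$replicates$a, data$replicates$b, icc_threshold)
  } else {
    feats <- feature_names(data$derivation)
    icc <- list(retained = feats,
                report = tibble(feature = feats, icc = NA_real_,
                                retained = TRUE))
  }
  stages$icc <- icc
  keep_cols <- c("sample_id", "label", icc$retained)
  derivation <- data$derivation[keep_cols]
  validation <- data$validation[keep_cols]

  # 2. iterative robust feature selection
  sel <- run_iterations(derivation, selection)
  robust <- select_robust_features(sel)
  stages$selection <- sel
  stages$robust_features <- robust
  if (length(robust) < 2) {
    abort(sprintf("stage 'selection' failed: only %d robust feature(s); artifacts so far returned",
                  length(robust)))
  }

  # 3. final split, standardization, six model families
  fs <- final_split(derivation[c("sample_id", "label", robust)], seeds[2])
  std <- fit_standardizer(fs$train)
  train_z <- standardize(fs$train, std)
  test_z <- standardize(fs$test, std)
  cohort_z <- standardize(derivation[c("sample_id", "label", robust)], std)
  valid_z <- standardize(validation[c("sample_id", "label", robust)], std)
  fam_seeds <- derive_seeds(seeds[3], length(families))
  assessments <- purrr::imap(setNames(as.list(families), families),
                             function(fam, nm) {
    i <- match(nm, families)
    model <- switch(fam,
      ridge = , lasso = , logistic = , lda =
        train_linear_scorer(train_z, fam, seed = fam_seeds[i]),
      knn = tune_knn(train_z, seed = fam_seeds[i]),
      svm = tune_svm(cohort_z, seed = fam_seeds[i]))
    if (fam == "svm") {
      assess_scorer(model, model$train, model$test,
                    n_permutations = selection$n_permutations,
                    seed = fam_seeds[i])
    } else {
      assess_scorer(model, train_z, test_z,
                    n_permutations = selection$n_permutations,
                    seed = fam_seeds[i])
    }
  })
  stages$assessments <- assessments
  best <- select_best_scorer(unname(assessments))
  stages$best <- best
  if (best$outcome != "ok") {
    abort("stage 'model selection' failed: no successful model")
  }
  best_model <- best$chosen$model

  # 4. RS on the full cohorts
  rs_der <- score_samples(best_model, cohort_z)
  rs_val <- score_samples(best_model, valid_z)

  # 5. clinical integration
  clin_der <- impute_clinical(data$clinical_derivation)
  clin_val <- impute_clinical(data$clinical_validation)
  screening <- screen_clinical(clin_der, clinical_alpha)
  flagged <- screening$variable[screening$flagged]
  stages$screening <- screening
  clin_der$RS <- unname(rs_der[clin_der$sample_id])
  clin_val$RS <- unname(rs_val[clin_val$sample_id])
  staged <- staged_logistic_selection(clin_der, c(flagged, "RS"),
                                      clinical_alpha)
  stages$staged <- staged
  if (!"RS" %in% staged$retained) {
    warn("RS not retained by the staged selection; forcing it into the final model")
    staged$retained <- union(staged$retained, "RS")
  }
  model <- fit_clin_rad(clin_der, staged$retained,
                        adjusted_cutoff = adjusted_cutoff)
  stages$clin_rad <- model

  # 6. evaluation on both cohorts
  p_der <- predict_clin_rad(model, clin_der)
  p_val <- predict_clin_rad(model, clin_val)
  eval_seeds <- derive_seeds(seeds[4], 2)
  evaluation <- list(
    derivation = performance_report(p_der, clin_der$label, model$cutoff),
    validation = performance_report(p_val, clin_val$label, model$cutoff),
    delong = delong_compare(p_der, clin_der$label, p_val, clin_val$label),
    perm_derivation = permutation_test_scores(p_der, clin_der$label,
                                              selection$n_permutations,
                                              eval_seeds[1]),
    perm_validation = permutation_test_scores(p_val, clin_val$label,
                                              selection$n_permutations,
                                              eval_seeds[2]),
    hl_derivation = hosmer_lemeshow(p_der, clin_der$label),
    hl_validation = hosmer_lemeshow(p_val, clin_val$label),
    calibration = calibration_bins(p_val, clin_val$label,
                                   n_bins = min(10, floor(length(p_val) / 5))),
    dca = decision_curve(p_val, clin_val$label),
    rs_only_validation = performance_report(
      rs_val, validation$label, youden_cutoff(rs_der, derivation$label)$cutoff)
  )
  stages$evaluation <- evaluation
  nomogram <- export_nomogram(model)
  stages$nomogram <- nomogram

  run <- structure(list(
    stages = stages, robust_features = robust,
    best_family = best$chosen$model_family,
    rs = list(derivation = rs_der, validation = rs_val),
    clin_rad_scores = list(derivation = p_der, validation = p_val),
    manifest = list(seed = selection$seed,
                    n_candidates = sel$n_candidates,
                    robust_features = robust,
                    best_family = best$chosen$model_family,
                    retained_clinical = staged$retained,
                    cutoff = model$cutoff,
                    r_version = as.character(getRversion()),
                    package_version = as.character(utils::packageVersion("radscore")))),
    class = "pipeline_run")
  if (!is.null(output_dir)) write_pipeline_artifacts(run, output_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d robust features | best family '%s' | Clin-Rad validation AUC %.3f>\n",
              length(x$robust_features), x$best_family,
              x$stages$evaluation$validation$auc))
  invisible(x)
}

write_pipeline_artifacts <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "scorers"), showWarnings = FALSE)
  st <- run$stages
  readr::write_csv(st$selection$counts, file.path(output_dir, "counts.csv"))
  jsonlite::write_json(
    list(counts = st$selection$counts,
         config = unclass(st$selection$config),
         n_candidates = st$selection$n_candidates,
         records = select(st$selection$records, -"features")),
    file.path(output_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  purrr::iwalk(st$assessments, function(a, nm) {
    if (!is.na(a$failure %||% NA)) return(invisible(NULL))
    m <- a$model
    payload <- if (inherits(m, "linear_scorer")) {
      list(family = m$family, coefficients = m$coefficients,
           intercept = m$intercept, lambda = m$lambda)
    } else if (inherits(m, "knn_model")) {
      list(family = "knn", k = m$k)
    } else {
      list(family = "svm", kernel = m$kernel, calibration = m$calibration)
    }
    payload$cutoff <- a$cutoff
    jsonlite::write_json(payload,
                         file.path(output_dir, "scorers", paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  })
  jsonlite::write_json(
    list(terms = st$clin_rad$terms, intercept = st$clin_rad$intercept,
         cutoff = st$clin_rad$cutoff, covariates = st$clin_rad$covariates),
    file.path(output_dir, "clin_rad_model.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(st$evaluation$derivation,
                   file.path(output_dir, "report_derivation.csv"))
  readr::write_csv(st$evaluation$validation,
                   file.path(output_dir, "report_validation.csv"))
  readr::write_csv(st$nomogram$axes, file.path(output_dir, "nomogram.csv"))
  readr::write_csv(as_tibble(st$evaluation$dca), file.path(output_dir, "dca.csv"))
  readr::write_csv(st$evaluation$calibration,
                   file.path(output_dir, "calibration.csv"))
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
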