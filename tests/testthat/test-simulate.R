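test_that("default cohorts have the study dimensions and balanced labels", {
  cfg <- sim_config()
  der <- simulate_feature_table(cfg, "derivation")
  val <- simulate_feature_table(cfg, "validation")
  expect_equal(nrow(der$table), 120)
  expect_equal(length(feature_names(der$table)), 107)
  expect_equal(sum(der$table$label == 1), 60)
  expect_equal(nrow(val$table), 50)
  expect_equal(sum(val$table$label == 1), 25)
  counts <- table(feature_classes(der$table))
  expect_equal(counts[["shape"]], 14)
  expect_equal(counts[["ngtdm"]], 5)
})

test_that("generators are deterministic under a fixed config seed", {
  cfg <- sim_config(seed = 77)
  expect_identical(simulate_feature_table(cfg, "derivation"),
                   simulate_feature_table(cfg, "derivation"))
  expect_identical(simulate_clinical_table(cfg, "derivation"),
                   simulate_clinical_table(cfg, "derivation"))
  # derivation and validation draws differ
  expect_false(identical(
    simulate_feature_table(cfg, "derivation")$table$glcm_Contrast[1:10],
    simulate_feature_table(cfg, "validation")$table$glcm_Contrast[1:10]))
})

test_that("planted structure is faithful: constants, duplicates, effects", {
  cfg <- sim_config(seed = 5)
  out <- simulate_feature_table(cfg, "derivation")
  tab <- out$table; truth <- out$truth
  for (f in truth$zero_variance) expect_equal(var(tab[[f]]), 0)
  # planted pairs correlate above 0.9 across seeded runs
  rs <- purrr::map_dbl(1:20, function(s) {
    o <- simulate_feature_table(sim_config(seed = s), "derivation")
    min(purrr::map2_dbl(o$truth$redundant_pairs$primary,
                        o$truth$redundant_pairs$duplicate,
                        ~ abs(cor(o$table[[.x]], o$table[[.y]]))))
  })
  expect_gte(mean(rs >= 0.9), 0.95)
})

test_that("single-feature AUC of a planted effect matches the closed form", {
  # two unit-variance normals shifted by d have AUC pnorm(d / sqrt(2));
  # monotone class transforms must not change it
  cfg <- sim_config(n_derivation = 5000, n_informative = 1, effect_sizes = 1,
                    n_redundant_pairs = 0, n_zero_variance = 0, seed = 11)
  tab <- simulate_feature_table(cfg, "derivation")$table
  f <- simulate_feature_table(cfg, "derivation")$truth$informative
  expect_equal(auc_delong(tab[[f]], tab$label)$auc, pnorm(1 / sqrt(2)),
               tolerance = 0.02)
})

test_that("null configuration yields null single-feature AUCs", {
  cfg <- sim_config(n_derivation = 2000, n_informative = 0,
                    effect_sizes = numeric(0), n_redundant_pairs = 0,
                    n_zero_variance = 0, seed = 3)
  tab <- simulate_feature_table(cfg, "derivation")$table
  aucs <- purrr::map_dbl(feature_names(tab),
                         ~ auc_delong(tab[[.x]], tab$label)$auc)
  # per-feature AUC has SD ~ 0.013 at n = 1000/1000
  expect_lt(mean(abs(aucs - 0.5)), 0.015)
  expect_lt(max(abs(aucs - 0.5)), 0.045)
})

test_that("inconsistent planted counts are rejected", {
  expect_error(sim_config(feature_class_counts = c(glcm = 5L),
                          n_informative = 4, n_redundant_pairs = 1),
               "exceeds n_features")
})

test_that("rater replicates have the variance-ratio ICC", {
  cfg <- sim_config(seed = 2)
  tab <- simulate_feature_table(cfg, "derivation")$table
  # noiseless replicates agree perfectly
  reps0 <- simulate_rater_replicates(tab, 0, seed = 4)
  expect_identical(reps0$a, reps0$b)
  flt <- icc_filter(reps0$a, reps0$b)
  expect_true(all(flt$report$icc == 1))
  # noise sd = feature sd implies ICC near 1/2 (sigma_b^2/(sigma_b^2+sigma_e^2))
  f <- "glcm_Contrast"
  s <- sd(tab[[f]])
  iccs <- purrr::map_dbl(1:10, function(sd_seed) {
    reps <- simulate_rater_replicates(tab[c("sample_id", "label", f)], s,
                                      seed = sd_seed)
    icc_21(cbind(reps$a[[f]], reps$b[[f]]))
  })
  expect_equal(mean(iccs), 0.5, tolerance = 0.1)
  # determinism
  expect_identical(simulate_rater_replicates(tab, 0.2, seed = 9),
                   simulate_rater_replicates(tab, 0.2, seed = 9))
  expect_error(simulate_rater_replicates(tab, -1), "rater_noise_sd")
})

test_that("clinical table has the 24 canonical covariates and planted shifts", {
  cfg <- sim_config(seed = 6)
  cl <- simulate_clinical_table(cfg, "derivation")
  expect_setequal(setdiff(names(cl), c("sample_id", "label")),
                  clinical_variables()$variable)
  expect_equal(nrow(cl), 120)
  # null effects: roughly alpha of variables flagged at large n
  cfg0 <- sim_config(n_derivation = 2000, clinical_effects = c(Age = 0),
                     seed = 8)
  cl0 <- simulate_clinical_table(cfg0, "derivation")
  sc <- screen_clinical(cl0, alpha = 0.05)
  expect_lte(sum(sc$flagged), 5)  # 24 vars at 5%: binomial, generous cap
  # unknown effect name rejected
  expect_error(sim_config(clinical_effects = c(NotAVariable = 1)),
               "unknown clinical variable")
})

test_that("screening recovers a majority of the seven planted variables", {
  cl <- simulate_clinical_table(sim_config(seed = 10), "derivation")
  sc <- screen_clinical(cl, alpha = 0.05)
  planted <- names(default_clinical_effects())
  expect_gte(sum(sc$flagged[sc$variable %in% planted]), 4)
})

test_that("missingness injection is binomial and spares identifiers", {
  cl <- simulate_clinical_table(sim_config(seed = 1), "derivation")
  expect_identical(inject_missingness(cl, 0), cl)
  out <- inject_missingness(cl, 0.1, seed = 3)
  n_cells <- nrow(out) * 24
  n_miss <- sum(is.na(out[setdiff(names(out), c("sample_id", "label"))]))
  # binomial 99% interval around rate * n_cells
  expect_gt(n_miss, qbinom(0.005, n_cells, 0.1))
  expect_lt(n_miss, qbinom(0.995, n_cells, 0.1))
  expect_false(anyNA(out$sample_id))
  expect_false(anyNA(out$label))
  expect_error(inject_missingness(cl, 1), "fraction")
})

test_that("YAML configs map onto sim_config", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_derivation: 40", "n_validation: 10", "n_informative: 2",
               "effect_sizes: [1.0, 0.5]", "n_redundant_pairs: 1",
               "n_zero_variance: 1", "seed: 99",
               "clinical_effects:", "  Renin: 0.5"), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_derivation, 40)
  expect_equal(cfg$effect_sizes, c(1.0, 0.5))
  expect_equal(cfg$clinical_effects, c(Renin = 0.5))
  expect_identical(simulate_feature_table(cfg, "derivation"),
                   simulate_feature_table(sim_config(
                     n_derivation = 40, n_validation = 10, n_informative = 2,
                     effect_sizes = c(1, 0.5), n_redundant_pairs = 1,
                     n_zero_variance = 1, seed = 99,
                     clinical_effects = c(Renin = 0.5)), "derivation"))
  writeLines("not_a_field: 3", path)
  expect_error(sim_config_from_yaml(path), "unknown sim_config field")
})

test_that("phantom mask matches the analytic ellipsoid volume", {
  ph <- simulate_phantom(dim = c(48, 48, 20), semi_axes = c(14, 10, 6),
                         spacing = c(1, 1, 5), seed = 7)
  expect_equal(sum(ph$mask), 4 / 3 * pi * 14 * 10 * 6, tolerance = 0.02)
  expect_equal(ph$spacing, c(1, 1, 5))
  expect_identical(simulate_phantom(seed = 7), simulate_phantom(seed = 7))
  expect_error(simulate_phantom(dim = c(10, 10, 10), semi_axes = c(9, 9, 9)),
               "fit inside")
})

test_that("phantom NIfTI round-trip preserves volume and spacing", {
  skip_if_not_installed("RNifti")
  ph <- simulate_phantom(dim = c(24, 24, 10), semi_axes = c(7, 6, 3),
                         spacing = c(1, 1, 5), seed = 2)
  td <- withr::local_tempdir()
  write_nifti_volume(ph, file.path(td, "img.nii.gz"), file.path(td, "msk.nii.gz"))
  back <- read_nifti_volume(file.path(td, "img.nii.gz"), file.path(td, "msk.nii.gz"))
  expect_equal(back$spacing[1:3], c(1, 1, 5))
  expect_equal(back$mask, ph$mask)
  expect_equal(back$image, ph$image, tolerance = 1e-6)
})
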