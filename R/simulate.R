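#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study conditions the pipeline was designed for: a derivation cohort of
#' 120 adrenals (60 lesional / 60 non-dominant), a temporal validation
#' cohort of 50 (25/25), and 107 radiomic features in the standard seven
#' classes (shape 14, firstorder 18, glcm 24, glrlm 16, glszm 16, gldm 14,
#' ngtdm 5).
#'
#' @param n_derivation,n_validation Cohort sizes (split evenly by label).
#' @param feature_class_counts Named integer vector, features per class.
#' @param n_informative Number of planted informative features.
#' @param effect_sizes Standardized mean differences (label 1 minus
#'   label 0) for the informative features; recycled to `n_informative`.
#' @param n_redundant_pairs Planted near-duplicate pairs.
#' @param redundant_r Latent correlation of each planted pair.
#' @param n_zero_variance Planted constant columns.
#' @param rater_noise_sd Default per-feature replicate noise (as a
#'   fraction of each feature's SD) for [simulate_rater_replicates()].
#' @param clinical_effects Named vector of standardized group differences
#'   for clinical covariates. The default plants `d = +/-0.8` in the seven
#'   discriminative variables, signed so the lesional (label 1) group has
#'   lower aldosterone indices and higher triglycerides and uric acid.
#' @param missing_rate Default clinical missingness fraction in `[0, 1)`.
#' @param block_correlation Exchangeable within-class latent correlation.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_derivation = 120, n_validation = 50,
                       feature_class_counts = radiomic_class_counts(),
                       n_informative = 5,
                       effect_sizes = 1.2,
                       n_redundant_pairs = 3,
                       redundant_r = 0.95,
                       n_zero_variance = 2,
                       rater_noise_sd = 0.15,
                       clinical_effects = default_clinical_effects(),
                       missing_rate = 0.05,
                       block_correlation = 0.3,
                       seed = 20120101) {
  n_features <- sum(feature_class_counts)
  effect_sizes <- rep_len(effect_sizes, n_informative)
  if (n_informative + 2 * n_redundant_pairs + n_zero_variance > n_features) {
    abort("planted structure exceeds n_features: n_informative + 2*n_redundant_pairs + n_zero_variance must be <= sum(feature_class_counts)")
  }
  if (n_derivation %% 2 || n_validation %% 2) {
    abort("cohort sizes must be even (labels are balanced by construction)")
  }
  assert_fraction(missing_rate, "missing_rate", open = FALSE)
  if (rater_noise_sd < 0) abort("rater_noise_sd must be >= 0")
  unknown <- setdiff(names(clinical_effects), clinical_variables()$variable)
  if (length(unknown)) {
    abort(sprintf("unknown clinical variable '%s' in clinical_effects", unknown[1]))
  }
  structure(list(
    n_derivation = n_derivation, n_validation = n_validation,
    n_features = n_features, feature_class_counts = feature_class_counts,
    n_informative = n_informative, effect_sizes = effect_sizes,
    n_redundant_pairs = n_redundant_pairs, redundant_r = redundant_r,
    n_zero_variance = n_zero_variance, rater_noise_sd = rater_noise_sd,
    clinical_effects = clinical_effects, missing_rate = missing_rate,
    block_correlation = block_correlation, seed = seed
  ), class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Accepts a YAML file whose top-level keys match the [sim_config()]
#' arguments (`clinical_effects` and `feature_class_counts` as named
#' maps); unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required to read YAML configs")
  }
  fields <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    abort(sprintf("unknown sim_config field '%s' in %s", unknown[1], path))
  }
  for (f in c("clinical_effects", "feature_class_counts")) {
    if (!is.null(fields[[f]])) fields[[f]] <- unlist(fields[[f]])
  }
  if (!is.null(fields$feature_class_counts)) {
    storage.mode(fields$feature_class_counts) <- "integer"
  }
  do.call(sim_config, fields)
}

#' @rdname sim_config
#' @param d Common standardized effect magnitude for the seven
#'   discriminative clinical variables.
#' @export
default_clinical_effects <- function(d = 0.8) {
  c("K+(Min.)" = d, "Echo-IVSd" = -d, "RF-UA" = d, "24h AE(Max.)" = -d,
    "Renin" = d, "Aldo-max" = -d, "BL-TG" = d)
}

sim_feature_names <- function(config) {
  counts <- config$feature_class_counts
  if (identical(counts, radiomic_class_counts())) {
    return(radiomic_feature_names())
  }
  unlist(purrr::imap(as.list(counts), function(k, cls) {
    paste0(cls, "_f", sprintf("%02d", seq_len(k)))
  }), use.names = FALSE)
}

# Skew-inducing monotone transform applied to these classes so the
# normality-adaptive correlation branch downstream sees non-normal margins.
skewed_classes <- c("glszm", "gldm")

#' Simulate a radiomic feature table with planted structure
#'
#' Draws a latent multivariate-normal table (exchangeable correlation
#' within each feature class), plants a standardized location shift on the
#' informative features for label-1 samples, overwrites redundant columns
#' as noisy near-copies of their partners and zero-variance columns as
#' constants, then applies a monotone exponential transform to the
#' `glszm`/`gldm` classes to create skewed margins. Monotone transforms
#' leave single-feature AUCs untouched, so an informative feature with
#' effect `d` has population AUC `pnorm(d / sqrt(2))` in every class.
#'
#' @param config A [sim_config()].
#' @param cohort `"derivation"` (n, seed substream 1) or `"validation"`.
#' @return List with `table` (feature tibble) and `truth` (list of
#'   `informative`, `redundant_pairs`, `zero_variance`, `effect_sizes`).
#' @export
simulate_feature_table <- function(config, cohort = c("derivation", "validation")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  n <- if (cohort == "derivation") config$n_derivation else config$n_validation
  seed <- derive_seeds(config$seed, 4)[if (cohort == "derivation") 1 else 2]
  feats <- sim_feature_names(config)
  p <- length(feats)
  classes <- sub("_.*$", "", feats)
  k <- config$n_informative
  m <- config$n_redundant_pairs
  z <- config$n_zero_variance
  informative <- feats[seq_len(k)]
  pair_idx <- if (m > 0) k + seq_len(2 * m) else integer(0)
  zero_idx <- if (z > 0) p - z + seq_len(z) else integer(0)
  labels <- rep(c(1L, 0L), each = n / 2)

  values <- with_seed(seed, {
    rho <- config$block_correlation
    x <- matrix(rnorm(n * p), n, p)
    for (cls in unique(classes)) {
      idx <- which(classes == cls)
      u <- rnorm(n)
      x[, idx] <- sqrt(rho) * u + sqrt(1 - rho) * x[, idx]
    }
    # planted effects on the latent (unit-variance) scale
    for (j in seq_len(k)) {
      x[labels == 1, j] <- x[labels == 1, j] + config$effect_sizes[j]
    }
    # near-duplicate pairs: even member is a noisy copy of the odd member
    r <- config$redundant_r
    for (q in seq_len(m)) {
      a <- k + 2 * q - 1; b <- k + 2 * q
      x[, b] <- r * x[, a] + sqrt(1 - r^2) * rnorm(n)
    }
    x[, zero_idx] <- 1
    x
  })
  skew <- classes %in% skewed_classes
  values[, skew] <- exp(0.5 * values[, skew])

  prefix <- if (cohort == "derivation") "D" else "V"
  tab <- as_tibble(as.data.frame(values))
  names(tab) <- feats
  tab <- bind_cols(tibble(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
                          label = labels), tab)
  truth <- list(
    informative = informative,
    redundant_pairs = if (m > 0)
      tibble(primary = feats[k + 2 * seq_len(m) - 1],
             duplicate = feats[k + 2 * seq_len(m)])
    else tibble(primary = character(), duplicate = character()),
    zero_variance = feats[zero_idx],
    effect_sizes = setNames(config$effect_sizes, informative)
  )
  list(table = validate_feature_table(tab), truth = truth)
}

#' Simulate two-rater replicate extractions
#'
#' Emulates the variability of two independent manual delineations: both
#' replicates are the base table plus independent per-feature Gaussian
#' noise, giving each feature an expected ICC of
#' `var_between / (var_between + var_noise)`.
#'
#' @param table Base feature table (the "true" extraction).
#' @param rater_noise_sd Noise SD per feature, recycled; interpreted on
#'   the feature's own scale (absolute units).
#' @param seed RNG seed.
#' @return List of two feature tables `a` and `b` with identical ids.
#' @export
simulate_rater_replicates <- function(table, rater_noise_sd, seed = 1L) {
  table <- validate_feature_table(table, require_label = "label" %in% names(table))
  if (any(rater_noise_sd < 0)) abort("rater_noise_sd must be >= 0")
  feats <- feature_names(table)
  sds <- rep_len(rater_noise_sd, length(feats))
  n <- nrow(table)
  with_seed(seed, {
    reps <- purrr::map(1:2, function(r) {
      out <- table
      for (j in seq_along(feats)) {
        if (sds[j] > 0) {
          out[[feats[j]]] <- out[[feats[j]]] + rnorm(n, 0, sds[j])
        }
      }
      out
    })
    list(a = reps[[1]], b = reps[[2]])
  })
}

clinical_marginals <- function() {
  tibble::tribble(
    ~variable,       ~dist,      ~p1,      ~p2,
    "Age",           "normal",   50,       10,
    "Gender",        "binary",   0.5,      NA,
    "Height",        "normal",   163,      8,
    "Weight",        "normal",   68,       12,
    "BMI",           "normal",   25.5,     3.5,
    "SBP",           "normal",   165,      20,
    "DBP",           "normal",   100,      13,
    "HTN Duration",  "lognormal", log(48), 1.0,
    "Aldo-max",      "lognormal", log(250), 0.6,
    "Renin",         "lognormal", log(5),  0.9,
    "K+(Min.)",      "normal",   3.1,      0.5,
    "Echo-IVSd",     "normal",   10.5,     1.3,
    "Echo-LVEF",     "normal",   63,       5,
    "RF-UA",         "normal",   360,      85,
    "RF-Cr",         "normal",   70,       16,
    "RF-EGFR",       "normal",   95,       16,
    "U-MA/Cr",       "lognormal", log(15), 1.0,
    "U-K 24h",       "normal",   45,       15,
    "U-K",           "normal",   30,       10,
    "BL-TC",         "normal",   4.7,      0.95,
    "BL-TG",         "lognormal", log(1.6), 0.5,
    "BL-LDL",        "normal",   2.8,      0.8,
    "BL-HDL",        "normal",   1.25,     0.3,
    "24h AE(Max.)",  "lognormal", log(10), 0.6
  )
}

#' Simulate a clinical covariate table
#'
#' Emits all 24 canonical covariates with synthetic marginal conventions
#' (normal for anthropometric and routine laboratory values, log-normal
#' for aldosterone/renin/triglycerides/urinary indices, 0/1 gender).
#' Group differences are planted only in the variables named in
#' `config$clinical_effects`, as standardized shifts (on the log scale for
#' log-normal variables, so the shift is monotone and rank-preserving).
#'
#' @inheritParams simulate_feature_table
#' @return A clinical tibble (`sample_id`, `label`, 24 covariates).
#' @export
simulate_clinical_table <- function(config, cohort = c("derivation", "validation")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  n <- if (cohort == "derivation") config$n_derivation else config$n_validation
  seed <- derive_seeds(config$seed, 4)[if (cohort == "derivation") 3 else 4]
  labels <- rep(c(1L, 0L), each = n / 2)
  marg <- clinical_marginals()
  eff <- config$clinical_effects
  cols <- with_seed(seed, purrr::pmap(marg, function(variable, dist, p1, p2) {
    d <- if (variable %in% names(eff)) eff[[variable]] else 0
    if (dist == "normal") {
      rnorm(n, p1 + d * p2 * (labels == 1), p2)
    } else if (dist == "lognormal") {
      rlnorm(n, p1 + d * p2 * (labels == 1), p2)
    } else {
      pr <- stats::plogis(stats::qlogis(p1) + d * (labels == 1))
      rbinom(n, 1, pr)
    }
  }))
  names(cols) <- marg$variable
  prefix <- if (cohort == "derivation") "D" else "V"
  tab <- bind_cols(tibble(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
                          label = labels), as_tibble(cols))
  validate_clinical_table(tab)
  tab
}

#' Inject missing-completely-at-random cells
#'
#' Each non-identifier cell is set to `NA` independently with probability
#' `rate`; `sample_id` and `label` are never touched.
#'
#' @param table A clinical (or feature) tibble.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  assert_fraction(rate, "rate", open = FALSE)
  if (rate == 0) return(as_tibble(table))
  vars <- setdiff(names(table), c("sample_id", "label"))
  out <- as_tibble(table)
  with_seed(seed, {
    for (v in vars) {
      hit <- runif(nrow(out)) < rate
      out[[v]][hit] <- NA
    }
  })
  out
}

#' Simulate a textured 3D phantom with an ellipsoidal mask
#'
#' Builds a small CT-like volume: Gaussian background, and inside an
#' ellipsoidal region a brighter, textured foreground (smooth sinusoidal
#' pattern plus noise) so texture matrices are non-trivial. Voxel spacing
#' is carried as metadata (default 1 x 1 x 5 mm, a thick-slice axial
#' geometry).
#'
#' @param dim Integer voxel dimensions, length 3.
#' @param semi_axes Ellipsoid semi-axes in voxel units.
#' @param center Ellipsoid center in voxel coordinates (default volume
#'   center).
#' @param spacing Voxel spacing in mm, length 3.
#' @param seed RNG seed.
#' @return A `phantom_volume` list: `image` and `mask` (3D arrays) and
#'   `spacing`.
#' @export
simulate_phantom <- function(dim = c(48, 48, 20), semi_axes = c(14, 10, 6),
                             center = (dim + 1) / 2, spacing = c(1, 1, 5),
                             seed = 1L) {
  stopifnot(length(dim) == 3, length(semi_axes) == 3, length(spacing) == 3)
  if (any(center - semi_axes < 1) || any(center + semi_axes > dim)) {
    abort("mask must fit inside the image")
  }
  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  inside <- ((idx$x - center[1]) / semi_axes[1])^2 +
    ((idx$y - center[2]) / semi_axes[2])^2 +
    ((idx$z - center[3]) / semi_axes[3])^2 <= 1
  if (!any(inside)) abort("empty mask")
  mask <- array(as.integer(inside), dim = dim)
  img <- with_seed(seed, {
    bg <- array(rnorm(prod(dim), -50, 15), dim = dim)
    tex <- 30 +
      20 * sin(2 * pi * idx$x / 7) * cos(2 * pi * idx$y / 9) +
      15 * sin(2 * pi * idx$z / 4) +
      1.2 * (idx$x - center[1]) +
      rnorm(prod(dim), 0, 10)
    out <- bg
    out[inside] <- tex[inside]
    out
  })
  structure(list(image = img, mask = mask, spacing = as.numeric(spacing)),
            class = "phantom_volume")
}

#' Write / read a phantom as NIfTI-1 image+mask pair
#'
#' Thin wrappers over RNifti; voxel spacing is recorded in the NIfTI
#' `pixdim` header.
#'
#' @param volume A `phantom_volume`.
#' @param image_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_nifti_volume <- function(volume, image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required for NIfTI input/output")
  }
  img <- RNifti::asNifti(volume$image)
  msk <- RNifti::asNifti(volume$mask)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::pixdim(msk) <- volume$spacing
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(image_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required for NIfTI input/output")
  }
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  structure(list(image = array(as.numeric(img), dim = dim(img)),
                 mask = array(as.integer(round(as.numeric(msk))), dim = dim(msk)),
                 spacing = RNifti::pixdim(img)),
            class = "phantom_volume")
}
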