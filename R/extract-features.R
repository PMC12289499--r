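#' The standard seven-class radiomic feature inventory
#'
#' `radiomic_class_counts()` gives the per-class feature counts of the
#' default extraction (shape 14, firstorder 18, glcm 24, glrlm 16,
#' glszm 16, gldm 14, ngtdm 5; 107 in total);
#' `radiomic_feature_names()` the canonical feature names, prefixed by
#' class.
#'
#' @param classes Character subset of the seven class names.
#' @return Named integer vector / character vector.
#' @export
radiomic_class_counts <- function() {
  c(shape = 14L, firstorder = 18L, glcm = 24L, glrlm = 16L, glszm = 16L,
    gldm = 14L, ngtdm = 5L)
}

#' @rdname radiomic_class_counts
#' @export
radiomic_feature_names <- function(classes = names(radiomic_class_counts())) {
  inv <- list(
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea",
              "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
              "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation", "Flatness"),
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "Percentile10", "Percentile90", "Maximum", "Mean",
                   "Median", "InterquartileRange", "Range",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                   "Uniformity"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy", "MCC",
             "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "RunPercentage", "GrayLevelVariance", "RunVariance",
              "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
              "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
  bad <- setdiff(classes, names(inv))
  if (length(bad)) abort(sprintf("unknown feature class '%s'", bad[1]))
  unlist(purrr::imap(inv[classes], function(v, cls) paste0(cls, "_", v)),
         use.names = FALSE)
}

#' Extraction configuration
#'
#' @param classes Feature classes to compute (default: all seven).
#' @param bin_width Intensity discretization bin width for texture and
#'   histogram features (default 25).
#' @param mask_label Mask value marking the region of interest.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(classes = names(radiomic_class_counts()),
                              bin_width = 25, mask_label = 1L) {
  bad <- setdiff(classes, names(radiomic_class_counts()))
  if (length(bad)) abort(sprintf("unknown feature class '%s'", bad[1]))
  if (bin_width <= 0) abort("bin_width must be positive")
  structure(list(classes = classes, bin_width = bin_width,
                 mask_label = as.integer(mask_label)),
            class = "extraction_config")
}

# half of the 26 3D neighbor offsets (the other half is implied by symmetry)
offsets13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g[g$dx > 0 | (g$dx == 0 & g$dy > 0) |
                (g$dx == 0 & g$dy == 0 & g$dz > 0), ])
}

offsets26 <- function() {
  o <- offsets13()
  rbind(o, -o)
}

# For a direction d, return the gray levels of all valid (v, v+d) pairs
# with both endpoints inside the mask. `g` is the discretized volume with
# 0 outside the mask.
shifted_pairs <- function(g, d) {
  dm <- dim(g)
  xr <- max(1, 1 - d[1]):min(dm[1], dm[1] - d[1])
  yr <- max(1, 1 - d[2]):min(dm[2], dm[2] - d[2])
  zr <- max(1, 1 - d[3]):min(dm[3], dm[3] - d[3])
  a <- g[xr, yr, zr, drop = FALSE]
  b <- g[xr + d[1], yr + d[2], zr + d[3], drop = FALSE]
  sel <- a > 0 & b > 0
  cbind(a[sel], b[sel])
}

#' Extract the radiomic feature vector of one region of interest
#'
#' Computes the standard seven-class radiomic feature set of a 3D
#' image/mask pair: shape descriptors from the mask geometry and voxel
#' spacing, first-order intensity statistics, and the five texture-matrix
#' families (GLCM, GLRLM, GLSZM, GLDM, NGTDM) on intensities discretized
#' with a fixed bin width. With all seven classes enabled on the
#' unfiltered image the result has exactly 107 named features. The
#' computation is fully deterministic.
#'
#' Texture matrices use 26-connectivity (13 unique directions at distance
#' 1, features averaged over directions for GLCM/GLRLM); shape surface
#' measures are voxel-based (exposed-face surface area, boundary-corrected
#' mesh volume).
#'
#' @param image 3D numeric array (or a `phantom_volume`, in which case
#'   `mask`/`spacing` default to its own).
#' @param mask 3D array; voxels equal to `config$mask_label` form the ROI.
#' @param spacing Voxel spacing in mm (length 3).
#' @param config An [extraction_config()].
#' @param sample_id Identifier for the output row.
#' @return One-row tibble: `sample_id` plus one column per feature.
#' @export
extract_features <- function(image, mask = NULL, spacing = c(1, 1, 1),
                             config = extraction_config(),
                             sample_id = "sample_1") {
  if (inherits(image, "phantom_volume")) {
    mask <- mask %||% image$mask
    spacing <- image$spacing
    image <- image$image
  }
  stopifnot(inherits(config, "extraction_config"))
  if (!identical(dim(image), dim(mask))) {
    abort("image and mask geometries differ")
  }
  roi <- mask == config$mask_label
  if (!any(roi)) abort("mask is empty at the configured label")

  # crop to the mask bounding box (+1 voxel pad) for texture work
  w <- which(roi, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, dim(image))
  img <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  vals <- img[msk]
  bw <- config$bin_width
  lev <- array(0L, dim = dim(img))
  lev[msk] <- as.integer(floor((img[msk] - min(vals)) / bw) + 1)
  ng <- max(lev)

  out <- list()
  for (cls in config$classes) {
    f <- switch(cls,
      shape = shape_features(roi, spacing),
      firstorder = firstorder_features(vals, bw, spacing),
      glcm = glcm_features(lev, ng),
      glrlm = glrlm_features(lev, ng),
      glszm = glszm_features(lev, ng),
      gldm = gldm_features(lev, ng),
      ngtdm = ngtdm_features(lev, ng))
    names(f) <- paste0(cls, "_", names(f))
    out <- c(out, as.list(f))
  }
  bind_cols(tibble(sample_id = sample_id), as_tibble(out))
}

#' Batch extraction over a manifest
#'
#' @param manifest Tibble with columns `sample_id`, `image_path`,
#'   `mask_path` (NIfTI files).
#' @inheritParams extract_features
#' @return Feature tibble, one row per manifest entry.
#' @export
extract_features_batch <- function(manifest, config = extraction_config()) {
  stopifnot(all(c("sample_id", "image_path", "mask_path") %in% names(manifest)))
  purrr::pmap_dfr(manifest, function(sample_id, image_path, mask_path, ...) {
    vol <- read_nifti_volume(image_path, mask_path)
    extract_features(vol, config = config, sample_id = sample_id)
  })
}

# ---- shape -----------------------------------------------------------------

shape_features <- function(roi, spacing) {
  vox <- prod(spacing)
  n <- sum(roi)
  dm <- dim(roi)
  # exposed faces along each axis give the voxel surface area, and the
  # boundary voxel count the mesh-volume correction (interior + half the
  # boundary layer)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  exposed <- 0
  boundary <- array(FALSE, dim = dm)
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    for (sgn in c(1L, -1L)) {
      nb <- shift_logical(roi, sgn * d)
      open_face <- roi & !nb
      exposed <- exposed + sum(open_face) * face_area[ax]
      boundary <- boundary | open_face
    }
  }
  n_boundary <- sum(boundary)
  mesh_volume <- (n - n_boundary / 2) * vox
  voxel_volume <- n * vox

  coords <- which(roi, arr.ind = TRUE)
  phys <- sweep(coords, 2, spacing, `*`)
  bcoords <- which(boundary, arr.ind = TRUE)
  bphys <- sweep(bcoords, 2, spacing, `*`)
  max3d <- max_pairwise_distance(bphys)
  # per-plane maxima: slice = row-column plane (fixed z), column = fixed y,
  # row = fixed x
  max2d <- vapply(3:1, function(ax) {
    max(vapply(split.data.frame(bphys, bcoords[, ax]), function(pp) {
      max_pairwise_distance(pp[, -ax, drop = FALSE])
    }, numeric(1)))
  }, numeric(1))

  ev <- if (nrow(phys) > 1) {
    sort(pmax(eigen(cov(phys), symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  } else c(0, 0, 0)
  axes <- 4 * sqrt(ev)

  c(MeshVolume = mesh_volume,
    VoxelVolume = voxel_volume,
    SurfaceArea = exposed,
    SurfaceVolumeRatio = exposed / mesh_volume,
    Sphericity = (36 * pi * mesh_volume^2)^(1 / 3) / exposed,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d[1],
    Maximum2DDiameterColumn = max2d[2],
    Maximum2DDiameterRow = max2d[3],
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

shift_logical <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dim = dm)
  xr <- max(1, 1 + d[1]):min(dm[1], dm[1] + d[1])
  yr <- max(1, 1 + d[2]):min(dm[2], dm[2] + d[2])
  zr <- max(1, 1 + d[3]):min(dm[3], dm[3] + d[3])
  out[xr, yr, zr] <- a[xr - d[1], yr - d[2], zr - d[3], drop = FALSE]
  out
}

max_pairwise_distance <- function(p, cap = 4000L) {
  if (nrow(p) < 2) return(0)
  if (nrow(p) > cap) p <- p[seq(1, nrow(p), length.out = cap), , drop = FALSE]
  g <- tcrossprod(p)
  sq <- diag(g)
  sqrt(max(outer(sq, sq, `+`) - 2 * g))
}

# ---- first order -----------------------------------------------------------

firstorder_features <- function(vals, bw, spacing) {
  n <- length(vals)
  hist_p <- tabulate(floor((vals - min(vals)) / bw) + 1)
  p <- hist_p[hist_p > 0] / n
  q <- quantile(vals, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  inner <- vals[vals >= q[1] & vals <= q[5]]
  mu <- mean(vals)
  v <- mean((vals - mu)^2)
  c(Energy = sum(vals^2),
    TotalEnergy = prod(spacing) * sum(vals^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(vals),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(vals),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (v > 0) mean((vals - mu)^3) / v^1.5 else 0,
    Kurtosis = if (v > 0) mean((vals - mu)^4) / v^2 else 0,
    Variance = v,
    Uniformity = sum(p^2))
}

# ---- GLCM ------------------------------------------------------------------

glcm_features <- function(lev, ng) {
  offs <- offsets13()
  feats <- matrix(NA_real_, nrow(offs), 24)
  for (k in seq_len(nrow(offs))) {
    pr <- shifted_pairs(lev, offs[k, ])
    if (nrow(pr) == 0) next
    cnt <- tabulate(pr[, 1] + (pr[, 2] - 1L) * ng, nbins = ng * ng)
    P <- matrix(cnt, ng, ng)
    P <- P + t(P)
    feats[k, ] <- glcm_from_matrix(P / sum(P), ng)
  }
  f <- colMeans(feats, na.rm = TRUE)
  names(f) <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
                "JointAverage", "JointEnergy", "JointEntropy", "MCC",
                "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
  f
}

glcm_from_matrix <- function(P, ng) {
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  # diagonal / cross-diagonal marginals
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(px)
  pij_marg <- outer(px, px)
  sel <- P > 0 & pij_marg > 0
  hxy1 <- -sum(P[sel] * log2(pij_marg[sel]))
  sel2 <- pij_marg > 0
  hxy2 <- -sum(pij_marg[sel2] * log2(pij_marg[sel2]))
  da <- sum(kd * pxy_diff)
  corr <- if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  # MCC: second largest eigenvalue of the gray-level transition kernel
  mcc <- {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      Pn <- P[nz, nz, drop = FALSE]
      pxn <- px[nz]
      Q <- (Pn / pxn) %*% (t(Pn) / pxn)
      e <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, e[2]))
    }
  }
  c(sum(i * j * P),
    sum((i + j - 2 * mu)^4 * P),
    sum((i + j - 2 * mu)^3 * P),
    sum((i + j - 2 * mu)^2 * P),
    sum((i - j)^2 * P),
    corr,
    da,
    ent(pxy_diff),
    sum((kd - da)^2 * pxy_diff),
    sum(P / (1 + abs(i - j))),
    sum(P / (1 + (i - j)^2)),
    sum(P / (1 + ((i - j) / ng)^2)),
    sum(P / (1 + abs(i - j) / ng)),
    imc1,
    imc2,
    sum(P[i != j] / (i[i != j] - j[i != j])^2),
    mu,
    sum(P^2),
    hxy,
    mcc,
    max(P),
    sum(ks * pxy_sum),
    ent(pxy_sum),
    sigma2)
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_features <- function(lev, ng) {
  dm <- dim(lev)
  np <- sum(lev > 0)
  coords <- which(array(TRUE, dm), arr.ind = TRUE)
  g <- as.vector(lev)
  offs <- offsets13()
  feats <- matrix(NA_real_, nrow(offs), 16)
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    steps <- rep(Inf, length(g))
    for (ax in 1:3) {
      if (d[ax] == 1) steps <- pmin(steps, coords[, ax] - 1)
      else if (d[ax] == -1) steps <- pmin(steps, dm[ax] - coords[, ax])
    }
    anchor <- coords - steps * matrix(d, nrow(coords), 3, byrow = TRUE)
    aid <- anchor[, 1] + (anchor[, 2] - 1) * dm[1] +
      (anchor[, 3] - 1) * dm[1] * dm[2]
    ord <- order(aid, steps)
    key <- aid[ord] * (ng + 1) + g[ord]
    r <- rle(key)
    glv <- r$values %% (ng + 1)
    keep <- glv > 0
    if (!any(keep)) next
    lens <- r$lengths[keep]; gl <- glv[keep]
    N <- matrix(tabulate(gl + (lens - 1) * ng, nbins = ng * max(lens)),
                nrow = ng)
    feats[k, ] <- run_zone_features(N, np, entropy_name = TRUE)
  }
  f <- colMeans(feats, na.rm = TRUE)
  names(f) <- c("ShortRunEmphasis", "LongRunEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                "RunPercentage", "GrayLevelVariance", "RunVariance",
                "RunEntropy", "LowGrayLevelRunEmphasis",
                "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                "LongRunHighGrayLevelEmphasis")
  f
}

# Shared feature formulas of the run-length and size-zone matrices:
# N[i, j] counts runs/zones of gray level i and length/size j.
run_zone_features <- function(N, np, entropy_name = FALSE) {
  nr <- sum(N)
  i <- row(N); j <- col(N)
  p <- N / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  c(sum(N / j^2) / nr,
    sum(N * j^2) / nr,
    sum(rowSums(N)^2) / nr,
    sum(rowSums(N)^2) / nr^2,
    sum(colSums(N)^2) / nr,
    sum(colSums(N)^2) / nr^2,
    nr / np,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    -sum(pe * log2(pe)),
    sum(N / i^2) / nr,
    sum(N * i^2) / nr,
    sum(N / (i^2 * j^2)) / nr,
    sum(N * i^2 / j^2) / nr,
    sum(N * j^2 / i^2) / nr,
    sum(N * i^2 * j^2) / nr)
}

# ---- GLSZM -----------------------------------------------------------------

glszm_features <- function(lev, ng) {
  dm <- dim(lev)
  np <- sum(lev > 0)
  offs <- offsets26()
  zones_g <- integer(0); zones_s <- integer(0)
  visited <- array(FALSE, dim = dm)
  idx_all <- which(lev > 0)
  coords_all <- which(lev > 0, arr.ind = TRUE)
  lin <- function(cc) cc[, 1] + (cc[, 2] - 1) * dm[1] + (cc[, 3] - 1) * dm[1] * dm[2]
  for (s in seq_along(idx_all)) {
    v <- idx_all[s]
    if (visited[v]) next
    level <- lev[v]
    frontier <- matrix(coords_all[s, ], 1, 3)
    visited[v] <- TRUE
    size <- 1L
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
        sweep(frontier, 2, offs[k, ], `+`)
      }))
      ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
        cand[, 2] >= 1 & cand[, 2] <= dm[2] &
        cand[, 3] >= 1 & cand[, 3] <= dm[3]
      cand <- cand[ok, , drop = FALSE]
      li <- lin(cand)
      keep <- !duplicated(li)
      cand <- cand[keep, , drop = FALSE]; li <- li[keep]
      sel <- lev[li] == level & !visited[li]
      cand <- cand[sel, , drop = FALSE]; li <- li[sel]
      visited[li] <- TRUE
      size <- size + length(li)
      frontier <- cand
    }
    zones_g <- c(zones_g, level); zones_s <- c(zones_s, size)
  }
  N <- matrix(tabulate(zones_g + (zones_s - 1L) * ng, nbins = ng * max(zones_s)),
              nrow = ng)
  f <- run_zone_features(N, np)
  names(f) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                "LargeAreaHighGrayLevelEmphasis")
  f
}

# ---- GLDM ------------------------------------------------------------------

gldm_features <- function(lev, ng, alpha = 0) {
  dm <- dim(lev)
  msk <- lev > 0
  dep <- array(0L, dim = dm)
  for (k in seq_len(nrow(offsets26()))) {
    d <- offsets26()[k, ]
    xr <- max(1, 1 - d[1]):min(dm[1], dm[1] - d[1])
    yr <- max(1, 1 - d[2]):min(dm[2], dm[2] - d[2])
    zr <- max(1, 1 - d[3]):min(dm[3], dm[3] - d[3])
    a <- lev[xr, yr, zr, drop = FALSE]
    b <- lev[xr + d[1], yr + d[2], zr + d[3], drop = FALSE]
    inc <- array(0L, dim = dm)
    inc[xr, yr, zr] <- as.integer(a > 0 & b > 0 & abs(a - b) <= alpha)
    dep <- dep + inc
  }
  g <- lev[msk]; dsz <- dep[msk] + 1L
  N <- matrix(tabulate(g + (dsz - 1L) * ng, nbins = ng * max(dsz)), nrow = ng)
  nz <- sum(N)
  i <- row(N); j <- col(N)
  p <- N / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  c(SmallDependenceEmphasis = sum(N / j^2) / nz,
    LargeDependenceEmphasis = sum(N * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(N)^2) / nz,
    DependenceNonUniformity = sum(colSums(N)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(N)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(pe * log2(pe)),
    LowGrayLevelEmphasis = sum(N / i^2) / nz,
    HighGrayLevelEmphasis = sum(N * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(N / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(N * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(N * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(N * i^2 * j^2) / nz)
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_features <- function(lev, ng) {
  dm <- dim(lev)
  msk <- lev > 0
  nb_sum <- array(0, dim = dm); nb_cnt <- array(0L, dim = dm)
  for (k in seq_len(nrow(offsets26()))) {
    d <- offsets26()[k, ]
    xr <- max(1, 1 - d[1]):min(dm[1], dm[1] - d[1])
    yr <- max(1, 1 - d[2]):min(dm[2], dm[2] - d[2])
    zr <- max(1, 1 - d[3]):min(dm[3], dm[3] - d[3])
    b <- lev[xr + d[1], yr + d[2], zr + d[3], drop = FALSE]
    s <- array(0, dim = dm); cnt <- array(0L, dim = dm)
    s[xr, yr, zr] <- b * (b > 0)
    cnt[xr, yr, zr] <- as.integer(b > 0)
    nb_sum <- nb_sum + s; nb_cnt <- nb_cnt + cnt
  }
  valid <- msk & nb_cnt > 0
  g <- lev[valid]
  abar <- nb_sum[valid] / nb_cnt[valid]
  nvp <- sum(valid)
  ni <- tabulate(g, nbins = ng)
  si <- vapply(seq_len(ng), function(i) sum(abs(i - abar[g == i])), numeric(1))
  pi_ <- ni / nvp
  present <- which(ni > 0)
  ngp <- length(present)
  coarse <- sum(pi_ * si)
  ii <- present
  pp <- pi_[present]; ss <- si[present]
  contrast <- if (ngp > 1) {
    (sum(outer(pp, pp) * outer(ii, ii, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(si) / nvp)
  } else 0
  busy_den <- sum(abs(outer(ii * pp, ii * pp, `-`)))
  busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
  pij_sum <- outer(pp, pp, `+`)
  complexity <- sum(abs(outer(ii, ii, `-`)) *
                      (outer(pp * ss, pp * ss, `+`) / pij_sum)) / nvp
  strength <- if (sum(si) > 0)
    sum(pij_sum * outer(ii, ii, function(a, b) (a - b)^2)) / sum(si) else 0
  c(Busyness = busyness,
    Coarseness = if (coarse > 0) 1 / coarse else 1e6,
    Complexity = complexity,
    Contrast = contrast,
    Strength = strength)
}
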