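# Scalar features from texture matrices, raw intensities, the discretized
# histogram and the binary mask. Formulas follow the standard reference
# definitions used across radiomics platforms; entropies use log base 2.
# Degenerate inputs (single voxel, zero variance) return 0 by convention so
# feature vectors stay finite.

.safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

.glcm_feature_names <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy",
  "angular_second_moment", "contrast", "dissimilarity",
  "inverse_difference", "inverse_difference_moment", "inverse_variance",
  "correlation", "autocorrelation",
  "cluster_tendency", "cluster_shade", "cluster_prominence",
  "information_correlation_1"
)

.glcm_features_one <- function(counts) {
  out <- setNames(numeric(length(.glcm_feature_names)), .glcm_feature_names)
  tot <- sum(counts)
  if (tot <= 0) return(out)
  p <- counts / tot
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)                       # == joint average (symmetric matrix)
  sigma2 <- sum((i - mu)^2 * p)

  dk <- abs(i - j)
  pd <- tapply(p, dk, sum)               # difference distribution over k=0..ng-1
  kd <- as.numeric(names(pd))
  da <- sum(kd * pd)
  sk <- i + j
  ps <- tapply(p, sk, sum)               # sum distribution over k=2..2ng
  ks <- as.numeric(names(ps))
  sa <- sum(ks * ps)

  out["joint_maximum"] <- max(p)
  out["joint_average"] <- mu
  out["joint_variance"] <- sigma2
  out["joint_entropy"] <- -sum(p * .safe_log2(p))
  out["difference_average"] <- da
  out["difference_variance"] <- sum((kd - da)^2 * pd)
  out["difference_entropy"] <- -sum(pd * .safe_log2(pd))
  out["sum_average"] <- sa
  out["sum_variance"] <- sum((ks - sa)^2 * ps)
  out["sum_entropy"] <- -sum(ps * .safe_log2(ps))
  out["angular_second_moment"] <- sum(p^2)
  out["contrast"] <- sum((i - j)^2 * p)
  out["dissimilarity"] <- sum(abs(i - j) * p)
  out["inverse_difference"] <- sum(p / (1 + abs(i - j)))
  out["inverse_difference_moment"] <- sum(p / (1 + (i - j)^2))
  off <- i != j
  out["inverse_variance"] <- sum(p[off] / (i[off] - j[off])^2)
  out["correlation"] <-
    if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 0
  out["autocorrelation"] <- sum(i * j * p)
  out["cluster_tendency"] <- sum((i + j - 2 * mu)^2 * p)
  out["cluster_shade"] <- sum((i + j - 2 * mu)^3 * p)
  out["cluster_prominence"] <- sum((i + j - 2 * mu)^4 * p)
  hxy <- out[["joint_entropy"]]
  hx <- -sum(px * .safe_log2(px))
  hxy1 <- -sum(p * .safe_log2(outer(px, px)))
  out["information_correlation_1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  out
}

.rl_feature_names <- function(prefix, runner) c(
  paste0("short_", runner, "_emphasis"), paste0("long_", runner, "_emphasis"),
  paste0("low_grey_level_", runner, "_emphasis"),
  paste0("high_grey_level_", runner, "_emphasis"),
  paste0("short_", runner, "_low_grey_level_emphasis"),
  paste0("short_", runner, "_high_grey_level_emphasis"),
  paste0("long_", runner, "_low_grey_level_emphasis"),
  paste0("long_", runner, "_high_grey_level_emphasis"),
  "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
  paste0(prefix, "_non_uniformity"), paste0(prefix, "_non_uniformity_normalised"),
  paste0(runner, "_percentage"),
  "grey_level_variance", paste0(prefix, "_variance"),
  paste0(runner, "_entropy")
)

.glrlm_feature_names <- .rl_feature_names("run_length", "run")
.glszm_feature_names <- sub("^short_zone", "small_zone", sub(
  "^long_zone", "large_zone", .rl_feature_names("zone_size", "zone")))

# shared structure of run-length and size-zone features: M[g, l] counts
# runs/zones of grey level g and length/size l; nvox = in-mask voxel count.
.rl_features_one <- function(counts, nvox, names) {
  out <- setNames(numeric(length(names)), names)
  ns <- sum(counts)
  if (ns <= 0) return(out)
  g <- row(counts); l <- col(counts)
  rg <- rowSums(counts)                  # per grey level
  rl <- colSums(counts)                  # per length/size
  lv <- seq_len(ncol(counts))
  gv <- seq_len(nrow(counts))
  out[1] <- sum(counts / l^2) / ns
  out[2] <- sum(counts * l^2) / ns
  out[3] <- sum(counts / g^2) / ns
  out[4] <- sum(counts * g^2) / ns
  out[5] <- sum(counts / (g^2 * l^2)) / ns
  out[6] <- sum(counts * g^2 / l^2) / ns
  out[7] <- sum(counts * l^2 / g^2) / ns
  out[8] <- sum(counts * (g * l)^2) / ns
  out[9] <- sum(rg^2) / ns
  out[10] <- sum(rg^2) / ns^2
  out[11] <- sum(rl^2) / ns
  out[12] <- sum(rl^2) / ns^2
  out[13] <- ns / nvox
  pg <- rg / ns
  mg <- sum(gv * pg)
  out[14] <- sum((gv - mg)^2 * pg)
  pl <- rl / ns
  ml <- sum(lv * pl)
  out[15] <- sum((lv - ml)^2 * pl)
  pm <- counts / ns
  out[16] <- -sum(pm * .safe_log2(pm))
  out
}

#' Texture features from a count matrix
#'
#' Computes the fixed family feature lists: 22 GLCM, 16 GLRLM or 16 GLSZM
#' features. For directional families (`glcm`, `glrlm`) pass the result of
#' the corresponding `compute_*` function; features are evaluated per
#' direction and averaged (directional aggregation by feature averaging).
#' Degenerate matrices (no valid pairs/runs) yield all-zero features.
#'
#' @param matrices Result of [compute_glcm()], [compute_glrlm()] (lists) or
#'   [compute_glszm()] (single `texture_matrix`); a bare `texture_matrix`
#'   is also accepted for any kind.
#' @param kind `"glcm"`, `"glrlm"` or `"glszm"`.
#' @param n_voxels In-mask voxel count; required for `glrlm`/`glszm`
#'   percentage features when not inferable.
#' @return Named numeric vector (length 22, 16 or 16).
#' @export
texture_features <- function(matrices, kind = c("glcm", "glrlm", "glszm"),
                             n_voxels = NULL) {
  kind <- match.arg(kind)
  mats <- if (inherits(matrices, "texture_matrix")) list(matrices)
          else if (!is.null(matrices$directional)) matrices$directional
          else list(matrices)
  per_dir <- lapply(mats, function(m) {
    counts <- m$counts
    switch(kind,
      glcm = .glcm_features_one(counts),
      glrlm = {
        nv <- if (is.null(n_voxels)) sum(counts * col(counts)) else n_voxels
        .rl_features_one(counts, nv, .glrlm_feature_names)
      },
      glszm = {
        nv <- if (is.null(n_voxels)) sum(counts * col(counts)) else n_voxels
        .rl_features_one(counts, nv, .glszm_feature_names)
      })
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

.intensity_feature_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum",
  "percentile10", "percentile90", "maximum", "interquartile_range", "range",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation",
  "quartile_coefficient_of_dispersion", "energy", "root_mean_square"
)

.histogram_feature_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum",
  "percentile10", "percentile90", "maximum", "mode", "interquartile_range",
  "range", "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation",
  "quartile_coefficient_of_dispersion", "entropy", "uniformity",
  "maximum_histogram_gradient"
)

.stat_block <- function(x) {
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n                 # population variance
  s <- sqrt(v)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  sub <- x[x >= q[1] & x <= q[5]]
  if (!length(sub)) sub <- q[3]  # tiny ROI: percentile window can be empty
  c(mean = m, variance = v,
    skewness = if (s > 0) sum((x - m)^3) / n / s^3 else 0,
    kurtosis = if (s > 0) sum((x - m)^4) / n / s^4 - 3 else 0,
    median = q[3], minimum = min(x), percentile10 = q[1], percentile90 = q[5],
    maximum = max(x), interquartile_range = q[4] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - m)),
    robust_mean_absolute_deviation = mean(abs(sub - mean(sub))),
    median_absolute_deviation = mean(abs(x - q[3])),
    coefficient_of_variation = if (m != 0) s / m else 0,
    quartile_coefficient_of_dispersion =
      if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0)
}

#' First-order features: intensity and histogram families
#'
#' The 18 intensity features are computed on the raw in-mask HU values; the
#' 20 histogram features on the fixed-bin-number discretized grey levels
#' (bin indices), matching the discretization used for the texture
#' families.
#'
#' @param volume A [ct_volume] or 3D array (HU).
#' @param mask Binary array aligned with the volume.
#' @param droi Optional precomputed [discretize_fbn()] result.
#' @param n_bins Bins used if `droi` is not supplied.
#' @return A list with named vectors `intensity` (18) and `histogram` (20).
#' @export
first_order_features <- function(volume, mask, droi = NULL, n_bins = 32L) {
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  mask <- array(as.logical(mask), dim(vox))
  if (!any(mask)) stop("empty mask")
  x <- vox[mask]
  n <- length(x)
  ib <- .stat_block(x)
  intensity <- c(ib, energy = sum(x^2), root_mean_square = sqrt(mean(x^2)))
  names(intensity) <- .intensity_feature_names

  if (is.null(droi)) droi <- discretize_fbn(vox, mask, n_bins)
  g <- droi$bins[droi$bins > 0L]
  hb <- .stat_block(g)
  counts <- tabulate(g, nbins = droi$n_bins)
  pg <- counts / n
  grad <- if (droi$n_bins >= 3)
    (counts[-(1:2)] - counts[seq_len(droi$n_bins - 2)]) / 2 else 0
  histogram <- c(hb["mean"], hb["variance"], hb["skewness"], hb["kurtosis"],
                 hb["median"], hb["minimum"], hb["percentile10"],
                 hb["percentile90"], hb["maximum"],
                 mode = which.max(counts),
                 hb["interquartile_range"], hb["range"],
                 hb["mean_absolute_deviation"],
                 hb["robust_mean_absolute_deviation"],
                 hb["median_absolute_deviation"],
                 hb["coefficient_of_variation"],
                 hb["quartile_coefficient_of_dispersion"],
                 entropy = -sum(pg * .safe_log2(pg)),
                 uniformity = sum(pg^2),
                 maximum_histogram_gradient = max(abs(grad)))
  names(histogram) <- .histogram_feature_names
  list(intensity = intensity, histogram = histogram)
}

.shape_feature_names <- c(
  "volume_mm3", "surface_area_mm2", "surface_to_volume_ratio", "sphericity",
  "compactness_1", "compactness_2", "spherical_disproportion",
  "maximum_3d_diameter_mm", "major_axis_length_mm", "minor_axis_length_mm",
  "least_axis_length_mm", "elongation", "flatness"
)

#' Shape (morphological) features of a binary mask
#'
#' Thirteen morphology features computed on the undiscretized mask:
#' voxel-counting volume, voxel-face surface area, their ratio, sphericity
#' and the related compactness measures, maximum 3D diameter (between
#' surface-voxel centers), and principal-axis lengths with elongation and
#' flatness (from the eigenvalues of the voxel-coordinate covariance,
#' axis length = 4 sqrt(lambda)).
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing in mm (length 3 or scalar).
#' @return Named numeric vector of length 13.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  nvox <- sum(mask)
  vol <- nvox * prod(spacing)

  # voxel-face surface area: faces adjacent to outside (grid edge counts)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  face <- function(axis) {
    shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))[[axis]]
    s <- shifts
    up <- pad[(2 + s[1]):(d[1] + 1 + s[1]), (2 + s[2]):(d[2] + 1 + s[2]),
              (2 + s[3]):(d[3] + 1 + s[3])]
    dn <- pad[(2 - s[1]):(d[1] + 1 - s[1]), (2 - s[2]):(d[2] + 1 - s[2]),
              (2 - s[3]):(d[3] + 1 - s[3])]
    sum(mask & !up) + sum(mask & !dn)
  }
  areas <- prod(spacing) / spacing        # face area normal to each axis
  surf <- face(1) * areas[1] + face(2) * areas[2] + face(3) * areas[3]

  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / surf
  comp1 <- vol / (sqrt(pi) * surf^1.5)
  comp2 <- 36 * pi * vol^2 / surf^3
  sphdis <- surf / (4 * pi * r_eq^2)

  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  # surface voxels: any 6-neighbour outside
  nb <- function(dx, dy, dz)
    pad[cbind(idx[, 1] + 1L + dx, idx[, 2] + 1L + dy, idx[, 3] + 1L + dz)]
  onsurf <- !(nb(1, 0, 0) & nb(-1, 0, 0) & nb(0, 1, 0) & nb(0, -1, 0) &
              nb(0, 0, 1) & nb(0, 0, -1))
  sc <- coords[onsurf, , drop = FALSE]
  maxd <- 0
  step <- 2000L
  for (a in seq(1, nrow(sc), by = step)) {
    blk <- sc[a:min(a + step - 1L, nrow(sc)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(sc^2), `+`) - 2 * blk %*% t(sc)
    maxd <- max(maxd, sqrt(max(0, max(d2))))
  }

  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(coords) * (nvox - 1) / nvox,
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  setNames(c(vol, surf, surf / vol, sphericity, comp1, comp2, sphdis,
             maxd, axes[1], axes[2], axes[3], elong, flat),
           .shape_feature_names)
}
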