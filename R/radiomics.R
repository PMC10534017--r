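# Top-level handcrafted feature extraction: 105 features in six families
# (13 shape, 18 intensity, 20 histogram, 22 GLCM, 16 GLRLM, 16 GLSZM).

.handcrafted_families <- c(shape = 13L, intensity = 18L, histogram = 20L,
                           glcm = 22L, glrlm = 16L, glszm = 16L)

#' Names of the 105 handcrafted features
#'
#' @return Character vector of `family__feature` names in stable order
#'   (shape, intensity, histogram, GLCM, GLRLM, GLSZM).
#' @export
handcrafted_feature_names <- function() {
  c(paste0("shape__", .shape_feature_names),
    paste0("intensity__", .intensity_feature_names),
    paste0("histogram__", .histogram_feature_names),
    paste0("glcm__", .glcm_feature_names),
    paste0("glrlm__", .glrlm_feature_names),
    paste0("glszm__", .glszm_feature_names))
}

#' Extract the handcrafted radiomic feature vector
#'
#' Computes all 105 handcrafted features from a GTV-masked CT volume on an
#' isotropic grid. Shape and intensity features use the raw mask/HU values;
#' histogram and texture families use the fixed-bin-number discretized ROI.
#' Texture families are direction-averaged over the 13 unique 3D
#' directions. Single-voxel or constant ROIs yield convention values (0)
#' for the texture families, with a warning attribute set.
#'
#' @param volume A [ct_volume] or 3D HU array (1 mm isotropic assumed if
#'   bare array).
#' @param mask Binary array aligned with the volume.
#' @param config A [radiomics_config()].
#' @return Named numeric vector of length 105 with a `families` attribute
#'   tagging each entry.
#' @export
extract_handcrafted <- function(volume, mask, config = radiomics_config()) {
  vol <- if (inherits(volume, "ct_volume")) volume else ct_volume(volume)
  mask <- array(as.logical(mask), dim(vol$voxels))
  if (!any(mask)) stop("empty mask")

  # crop to the mask bounding box (plus one voxel) for the texture work
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(mask))
  sub_v <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  droi <- discretize_fbn(sub_v, sub_m, config$n_bins)
  fo <- first_order_features(sub_v, sub_m, droi = droi)
  sh <- shape_features(mask, vol$spacing)

  degenerate <- droi$n_voxels < 2
  if (degenerate) {
    glcm_f <- setNames(numeric(22), .glcm_feature_names)
    glrlm_f <- setNames(numeric(16), .glrlm_feature_names)
    glszm_f <- setNames(numeric(16), .glszm_feature_names)
  } else {
    glcm_f <- texture_features(compute_glcm(droi, config), "glcm")
    glrlm_f <- texture_features(compute_glrlm(droi, config), "glrlm",
                                n_voxels = droi$n_voxels)
    glszm_f <- texture_features(compute_glszm(droi, config), "glszm",
                                n_voxels = droi$n_voxels)
  }

  out <- c(sh, fo$intensity, fo$histogram, glcm_f, glrlm_f, glszm_f)
  names(out) <- handcrafted_feature_names()
  attr(out, "families") <- rep(names(.handcrafted_families),
                               .handcrafted_families)
  if (degenerate) attr(out, "degenerate_roi") <- TRUE
  out
}
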