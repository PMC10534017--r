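# Fixed-bin-number discretization and texture-count matrices (GLCM, GLRLM,
# GLSZM) over the 13 unique directions of the 26-neighbourhood.

# the 13 non-opposite unit offsets of the 26-neighbourhood
.directions13 <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,
  1, 0, 1,   1, 0, -1,
  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,  1, -1, -1
), ncol = 3, byrow = TRUE)

#' Radiomics configuration
#'
#' @param n_bins Number of grey-level bins for fixed-bin-number
#'   discretization (default 32).
#' @param glcm_distance Co-occurrence offset length in voxels (default 1).
#' @param aggregation How directional texture features are combined;
#'   only `"average"` (feature-wise mean over the 13 directions) is
#'   implemented.
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(n_bins = 32L, glcm_distance = 1L,
                             aggregation = "average") {
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins),
                 glcm_distance = as.integer(glcm_distance),
                 directions = .directions13, aggregation = aggregation),
            class = "radiomics_config")
}

#' Fixed-bin-number discretization of a masked ROI
#'
#' Maps in-mask intensities onto `n_bins` equal-width bins spanning the ROI
#' range: `bin(x) = floor(n_bins * (x - min) / (max - min)) + 1`, with the
#' maximum mapped to `n_bins`. A constant ROI maps every voxel to bin 1.
#'
#' @param volume A [ct_volume] or 3D array.
#' @param mask Logical/binary array aligned with the volume.
#' @param n_bins Number of bins.
#' @return A list of class `droi`: `bins` (integer array, 0 outside the
#'   mask), `n_bins`, `n_voxels`.
#' @export
discretize_fbn <- function(volume, mask, n_bins = 32L) {
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  mask <- array(as.logical(mask), dim(vox))
  if (!any(mask)) stop("empty mask: nothing to discretize")
  x <- vox[mask]
  rng <- range(x)
  bins <- array(0L, dim(vox))
  if (rng[2] > rng[1]) {
    b <- floor(n_bins * (x - rng[1]) / (rng[2] - rng[1])) + 1L
    b[b > n_bins] <- as.integer(n_bins)
    bins[mask] <- as.integer(b)
  } else {
    bins[mask] <- 1L
  }
  structure(list(bins = bins, n_bins = as.integer(n_bins),
                 n_voxels = sum(mask)), class = "droi")
}

.as_texture_matrix <- function(counts, kind, direction = NULL) {
  structure(list(kind = kind, counts = counts, direction = direction),
            class = "texture_matrix")
}

#' Grey-level co-occurrence matrices
#'
#' Symmetric co-occurrence counts at the configured distance for each of the
#' 13 unique 3D directions, restricted to in-mask voxel pairs, plus the
#' element-wise mean of the directional matrices.
#'
#' @param droi A [discretize_fbn()] result.
#' @param config A [radiomics_config()].
#' @return A list with `directional` (13 `texture_matrix` objects) and
#'   `aggregated` (their element-wise mean).
#' @export
compute_glcm <- function(droi, config = radiomics_config()) {
  stopifnot(inherits(droi, "droi"))
  dirs <- config$directions * config$glcm_distance
  mats <- lapply(seq_len(nrow(dirs)), function(i)
    .as_texture_matrix(.glcm_counts(droi$bins, droi$n_bins, as.integer(dirs[i, ])),
                       "glcm", dirs[i, ]))
  agg <- Reduce(`+`, lapply(mats, `[[`, "counts")) / length(mats)
  list(directional = mats, aggregated = .as_texture_matrix(agg, "glcm"))
}

#' Grey-level run-length matrices
#'
#' Run counts per grey level and run length along each of the 13 directions.
#'
#' @inheritParams compute_glcm
#' @return A list with `directional` (13 `texture_matrix` objects) and
#'   `aggregated` (their element-wise mean, padded to a common length).
#' @export
compute_glrlm <- function(droi, config = radiomics_config()) {
  stopifnot(inherits(droi, "droi"))
  dirs <- config$directions
  mats <- lapply(seq_len(nrow(dirs)), function(i)
    .as_texture_matrix(.glrlm_counts(droi$bins, droi$n_bins, as.integer(dirs[i, ])),
                       "glrlm", dirs[i, ]))
  maxl <- max(vapply(mats, function(m) ncol(m$counts), integer(1)))
  padded <- lapply(mats, function(m) {
    cbind(m$counts, matrix(0L, nrow(m$counts), maxl - ncol(m$counts)))
  })
  agg <- Reduce(`+`, padded) / length(padded)
  list(directional = mats, aggregated = .as_texture_matrix(agg, "glrlm"))
}

#' Grey-level size-zone matrix
#'
#' Zone counts per grey level and zone size under 26-connectivity. Size
#' zones are direction-free, so a single matrix is returned.
#'
#' @inheritParams compute_glcm
#' @return A `texture_matrix` of kind `"glszm"`.
#' @export
compute_glszm <- function(droi, config = radiomics_config()) {
  stopifnot(inherits(droi, "droi"))
  .as_texture_matrix(.glszm_counts(droi$bins, droi$n_bins), "glszm")
}
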