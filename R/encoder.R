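# 3D U-Net encoder for deep feature extraction: five convolutional blocks
# (two 3x3x3 convolutions + ReLU each), 2x2x2 max pooling between blocks,
# and global average pooling of the final 512-channel map. An 80 mm VOI at
# 1 mm spacing maps 80 -> 40 -> 20 -> 10 -> 5 spatially. Weights are either
# loaded from a tensor archive or drawn from a seeded He-normal
# initialization so the pipeline runs with no external download.

#' Encoder configuration
#'
#' @param voi_mm Cube side of the input volume-of-interest in mm.
#' @param channels Channel progression of the five blocks.
#' @param hu_window HU clipping window mapped linearly onto `[0, 1]`.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(voi_mm = 80L,
                           channels = c(32L, 64L, 128L, 256L, 512L),
                           hu_window = c(-1000, 1000)) {
  structure(list(voi_mm = as.integer(voi_mm), channels = as.integer(channels),
                 hu_window = hu_window),
            class = "encoder_config")
}

# expected tensor names and shapes for a given configuration
.encoder_layout <- function(config = encoder_config()) {
  ch <- config$channels
  cin <- c(1L, head(rep(ch, each = 2), -1))
  cout <- rep(ch, each = 2)
  names <- sprintf("block%d_conv%d", rep(seq_along(ch), each = 2), 1:2)
  lapply(setNames(seq_along(names), names), function(i)
    list(weight = c(cout[i], cin[i], 3L, 3L, 3L), bias = cout[i]))
}

#' Initialize encoder weights randomly
#'
#' He-normal initialization (SD `sqrt(2 / fan_in)`), zero biases,
#' reproducible from the seed. Used as the default weight source when no
#' pre-trained archive is supplied.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return Named list of layers, each `list(weight = 5D array, bias)`.
#' @export
init_encoder_weights <- function(config = encoder_config(), seed = 1L) {
  layout <- .encoder_layout(config)
  with_seed(seed, {
    w <- lapply(layout, function(l) {
      fan_in <- prod(l$weight[-1])
      list(weight = array(rnorm(prod(l$weight), sd = sqrt(2 / fan_in)),
                          l$weight),
           bias = numeric(l$bias))
    })
    structure(w, class = "encoder_weights", config = config, source = "random",
              seed = seed)
  })
}

#' Load pre-trained encoder weights
#'
#' Reads a weight archive (an RDS file holding a named list of
#' `list(weight, bias)` tensors, one entry per `blockB_convC` layer) and
#' validates every tensor shape against the configured architecture. A
#' converter from external checkpoint formats only needs to emit this
#' layout.
#'
#' @param path Path to the weight archive; `NULL` falls back to
#'   [init_encoder_weights()] with `seed`.
#' @param config An [encoder_config()].
#' @param seed Seed for the random fallback.
#' @return An `encoder_weights` object.
#' @export
load_pretrained <- function(path = NULL, config = encoder_config(), seed = 1L) {
  if (is.null(path)) return(init_encoder_weights(config, seed))
  if (!file.exists(path)) stop("weight archive not found: ", path)
  w <- readRDS(path)
  layout <- .encoder_layout(config)
  for (nm in names(layout)) {
    if (is.null(w[[nm]]))
      stop("weight archive is missing tensor '", nm, "'")
    got <- dim(w[[nm]]$weight)
    want <- layout[[nm]]$weight
    if (is.null(got) || length(got) != 5L || any(got != want))
      stop("shape mismatch for tensor '", nm, "': expected (",
           paste(want, collapse = ","), "), got (",
           paste(got, collapse = ","), ")")
    if (length(w[[nm]]$bias) != layout[[nm]]$bias)
      stop("bias length mismatch for tensor '", nm, "'")
  }
  structure(w[names(layout)], class = "encoder_weights", config = config,
            source = path)
}

#' Save encoder weights
#'
#' @param weights An `encoder_weights` object.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_encoder_weights <- function(weights, path) {
  saveRDS(unclass(weights), path)
  invisible(path)
}

#' Crop the volume-of-interest around the tumor
#'
#' Extracts a cube of `voi_mm` voxels (1 mm grid) centered on the mask
#' centroid (rounded to the nearest voxel); regions outside the scanned
#' volume are padded with -1000 HU (air).
#'
#' @param volume A [ct_volume] or 3D array on a 1 mm grid.
#' @param mask Binary array aligned with the volume.
#' @param voi_mm VOI side length in mm/voxels.
#' @param pad_hu Padding value for out-of-volume voxels.
#' @return 3D array of side `voi_mm`.
#' @export
crop_voi <- function(volume, mask, voi_mm = 80L, pad_hu = -1000) {
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  mask <- array(as.logical(mask), dim(vox))
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  ext <- apply(idx, 2, max) - apply(idx, 2, min) + 1L
  if (any(ext > voi_mm))
    stop("GTV extent (", paste(ext, collapse = "x"),
         " voxels) exceeds the ", voi_mm, " mm VOI")
  centroid <- round(colMeans(idx))
  lo <- as.integer(centroid - floor(voi_mm / 2) + (voi_mm %% 2 == 0))
  out <- array(pad_hu, rep(as.integer(voi_mm), 3))
  src_lo <- pmax(lo, 1L)
  src_hi <- pmin(lo + voi_mm - 1L, dim(vox))
  if (all(src_hi >= src_lo)) {
    dst_lo <- src_lo - lo + 1L
    dst_hi <- src_hi - lo + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vox[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out
}

#' Normalize a HU block for the encoder
#'
#' Clips to the configured HU window and maps it linearly onto `[0, 1]`.
#'
#' @param block 3D HU array.
#' @param hu_window Clipping window, default `c(-1000, 1000)`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_input <- function(block, hu_window = c(-1000, 1000)) {
  (pmin(pmax(block, hu_window[1]), hu_window[2]) - hu_window[1]) /
    (hu_window[2] - hu_window[1])
}

#' Augmentation specification
#'
#' @param rotation_deg Maximum rotation magnitude (degrees) about a random
#'   axis.
#' @param scale_range Isotropic scale factor range.
#' @param flip_axes Axes (subset of 1:3) eligible for random flips.
#' @param noise_sd Additive Gaussian noise SD in normalized intensity units.
#' @param multiplicity Number of blocks returned per input (the first is
#'   always the unmodified input).
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_deg = 10, scale_range = c(0.9, 1.1),
                              flip_axes = 1:3, noise_sd = 0.01,
                              multiplicity = 1L) {
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  structure(list(rotation_deg = rotation_deg, scale_range = scale_range,
                 flip_axes = flip_axes, noise_sd = noise_sd,
                 multiplicity = as.integer(multiplicity)),
            class = "augmentation_spec")
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
.rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' 3D augmentation of a normalized block
#'
#' Draws `multiplicity` variants: the original followed by independently
#' sampled rotation + scaling + flips (resampled trilinearly about the
#' block center) with additive Gaussian noise. Deterministic in `seed`.
#'
#' @param block Normalized 3D array.
#' @param spec An [augmentation_spec()].
#' @param seed Integer seed.
#' @return List of `spec$multiplicity` arrays, the first being `block`.
#' @export
augment_3d <- function(block, spec = augmentation_spec(), seed = 1L) {
  d <- dim(block)
  ctr <- (d - 1) / 2
  with_seed(seed, {
    out <- vector("list", spec$multiplicity)
    out[[1]] <- block
    for (m in seq_len(spec$multiplicity)[-1]) {
      theta <- runif(1, -spec$rotation_deg, spec$rotation_deg) * pi / 180
      axis <- rnorm(3)
      s <- runif(1, spec$scale_range[1], spec$scale_range[2])
      R <- .rotation_matrix(axis, theta) / s
      flip <- diag(ifelse(1:3 %in% spec$flip_axes & runif(3) < 0.5, -1, 1))
      A <- R %*% flip
      if (max(abs(A - diag(3))) < 1e-12) {
        b <- block
      } else {
        aff <- cbind(A, ctr - A %*% ctr)
        b <- .affine_sample(block, d, aff, 0L, 0, FALSE)
      }
      if (spec$noise_sd > 0) b <- b + rnorm(length(b), sd = spec$noise_sd)
      out[[m]] <- array(b, d)
    }
    out
  })
}

#' Encode a VOI block into 512 deep features
#'
#' Runs the five-block encoder and global-average-pools the final feature
#' map channel-wise. Input spatial dimensions must be divisible by 16
#' (four poolings).
#'
#' @param block Normalized 3D array (values in `[0, 1]`).
#' @param weights An `encoder_weights` object.
#' @param config An [encoder_config()] (defaults to the weights' config).
#' @param return_map Also return the pre-pooling feature map.
#' @return Named numeric vector of length `tail(channels, 1)` (512 by
#'   default), or a list `(features, map)` when `return_map = TRUE`.
#' @export
encode_deep_features <- function(block, weights, config = NULL,
                                 return_map = FALSE) {
  if (is.null(config)) config <- attr(weights, "config")
  if (is.null(config)) config <- encoder_config()
  d <- dim(block)
  if (length(d) != 3L) stop("block must be a 3D array")
  if (any(d %% 16L != 0L))
    stop("block dimensions (", paste(d, collapse = "x"),
         ") must be divisible by 16 (four 2x pooling stages)")
  x <- array(block, c(1L, d))
  nb <- length(config$channels)
  for (b in seq_len(nb)) {
    for (cv in 1:2) {
      layer <- weights[[sprintf("block%d_conv%d", b, cv)]]
      x <- .conv3d_same(x, layer$weight, layer$bias, TRUE)
    }
    if (b < nb) x <- .maxpool3d(x)
  }
  feat <- rowMeans(matrix(x, nrow = dim(x)[1]))
  names(feat) <- sprintf("deep__f%03d", seq_along(feat))
  if (return_map) list(features = feat, map = x) else feat
}

#' Deep features for one volume/mask pair
#'
#' Convenience wrapper: crop the VOI, normalize, encode.
#'
#' @param volume A [ct_volume] on a 1 mm grid.
#' @param mask Binary mask aligned with the volume.
#' @param weights An `encoder_weights` object.
#' @param config An [encoder_config()].
#' @return Named numeric vector of deep features.
#' @export
deep_features <- function(volume, mask, weights, config = encoder_config()) {
  block <- crop_voi(volume, mask, voi_mm = config$voi_mm)
  encode_deep_features(normalize_input(block, config$hu_window), weights,
                       config)
}
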