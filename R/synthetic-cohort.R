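# Synthetic CT phantom cohorts: ellipsoidal tumors in lung-like noise with
# a configurable planted image-outcome effect, plus clinical covariates
# matching the summary statistics of the two study cohorts (83 subjects /
# 7 local failures resected; 84 / 9 treated with SBRT).

#' Cohort generation configuration
#'
#' Builds the full parameter set for [generate_cohort()]. The `surgery` and
#' `sbrt` presets reproduce the published cohort structure: subject and
#' event counts, tumor-size distribution (mean 1.75 cc in 0.6-6 cc, and
#' mean 2.36 cc in 0.9-4.7 cc respectively), sex fractions and age ranges.
#' The planted effect adds `effect_mean_hu` to tumor HU and multiplies the
#' intratumoral texture amplitude by `effect_texture` for event-positive
#' subjects only; with `effect_mean_hu = 0, effect_texture = 1` labels are
#' independent of image content.
#'
#' @param preset `"surgery"` or `"sbrt"`.
#' @param n_subjects,n_events Cohort size and number of positive labels.
#' @param tumor_volume_range_cc Truncation range (cc) of the tumor-size
#'   distribution.
#' @param tumor_volume_mean_cc Target mean tumor size (cc).
#' @param background_hu,tumor_hu_base Mean HU of lung background and tumor.
#' @param noise_sd_hu Additive noise SD (HU); also the baseline amplitude
#'   of the smooth intratumoral texture.
#' @param effect_mean_hu HU shift planted in event-positive tumors.
#' @param effect_texture Texture-amplitude multiplier for event-positive
#'   tumors.
#' @param age_range,male_fraction,cci_range Demographic sampling ranges.
#' @param dose_schemes For `sbrt`: list of `c(dose_per_fraction_gy,
#'   n_fractions)` schemes sampled uniformly; `NULL` for surgery.
#' @param shape Voxel grid dimensions (1 mm isotropic).
#' @param seed Integer master seed for the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("surgery", "sbrt"),
                          n_subjects = NULL, n_events = NULL,
                          tumor_volume_range_cc = NULL,
                          tumor_volume_mean_cc = NULL,
                          background_hu = -800, tumor_hu_base = 20,
                          noise_sd_hu = 20,
                          effect_mean_hu = 0, effect_texture = 1,
                          age_range = NULL, male_fraction = NULL,
                          cci_range = c(0, 6), dose_schemes = NULL,
                          shape = c(128L, 128L, 128L), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "surgery") {
    if (is.null(n_subjects)) n_subjects <- 83L
    if (is.null(n_events)) n_events <- 7L
    if (is.null(tumor_volume_range_cc)) tumor_volume_range_cc <- c(0.6, 6)
    if (is.null(tumor_volume_mean_cc)) tumor_volume_mean_cc <- 1.75
    if (is.null(age_range)) age_range <- c(51, 88)
    if (is.null(male_fraction)) male_fraction <- 0.47
  } else {
    if (is.null(n_subjects)) n_subjects <- 84L
    if (is.null(n_events)) n_events <- 9L
    if (is.null(tumor_volume_range_cc)) tumor_volume_range_cc <- c(0.9, 4.7)
    if (is.null(tumor_volume_mean_cc)) tumor_volume_mean_cc <- 2.36
    if (is.null(age_range)) age_range <- c(52, 100)
    if (is.null(male_fraction)) male_fraction <- 0.56
    if (is.null(dose_schemes))
      dose_schemes <- list(c(10, 5), c(12.5, 4), c(18, 3), c(20, 3))
  }
  cfg <- list(preset = preset, n_subjects = as.integer(n_subjects),
              n_events = as.integer(n_events),
              tumor_volume_range_cc = tumor_volume_range_cc,
              tumor_volume_mean_cc = tumor_volume_mean_cc,
              background_hu = background_hu, tumor_hu_base = tumor_hu_base,
              noise_sd_hu = noise_sd_hu, effect_mean_hu = effect_mean_hu,
              effect_texture = effect_texture, age_range = age_range,
              male_fraction = male_fraction, cci_range = cci_range,
              dose_schemes = dose_schemes, shape = as.integer(shape),
              seed = as.integer(seed))
  if (cfg$n_events > cfg$n_subjects)
    stop("n_events (", cfg$n_events, ") exceeds n_subjects (", cfg$n_subjects, ")")
  if (cfg$noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  if (diff(tumor_volume_range_cc) < 0 || tumor_volume_range_cc[1] <= 0)
    stop("tumor_volume_range_cc must be positive and increasing")
  class(cfg) <- "cohort_config"
  cfg
}

# separable Gaussian blur of a 3D array, sigma in voxels
.gauss_blur3 <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  x <- apply(x, c(2, 3), pad_filter); dim(x) <- d
  x <- aperm(apply(x, c(1, 3), pad_filter), c(2, 1, 3)); dim(x) <- d
  x <- aperm(apply(x, c(1, 2), pad_filter), c(2, 3, 1)); dim(x) <- d
  x
}

#' Generate a single CT phantom
#'
#' Places a randomly oriented ellipsoidal tumor of the requested volume in a
#' lung-like noisy background. Tumor voxels take
#' `tumor_hu_base + mean_shift_hu` plus a smooth random texture
#' (Gaussian-blurred white noise, FWHM 3 mm) with amplitude
#' `heterogeneity * noise_sd_hu`; the background is `background_hu` plus
#' white Gaussian noise.
#'
#' @param shape Grid dimensions (voxels, 1 mm isotropic).
#' @param tumor_volume_cc Requested tumor volume in cc (realized within 10%).
#' @param heterogeneity Dimensionless texture-amplitude multiplier.
#' @param mean_shift_hu HU shift added to all tumor voxels.
#' @param seed Integer seed; the same seed reproduces the phantom exactly.
#' @param background_hu,tumor_hu_base,noise_sd_hu Intensity model, in HU.
#' @param margin_mm Minimum clearance between tumor surface and grid faces.
#' @return A list with `volume` ([ct_volume]), `mask` (logical 3D array) and
#'   `center` (tumor center, voxel coordinates).
#' @export
generate_phantom <- function(shape = c(128L, 128L, 128L), tumor_volume_cc = 1.75,
                             heterogeneity = 1, mean_shift_hu = 0, seed = 1L,
                             background_hu = -800, tumor_hu_base = 20,
                             noise_sd_hu = 20, margin_mm = 8) {
  stopifnot(length(shape) == 3L, tumor_volume_cc > 0, noise_sd_hu >= 0)
  with_seed(seed, {
    v_mm3 <- tumor_volume_cc * 1000
    r2 <- runif(1, 0.6, 1); r3 <- runif(1, 0.6, 1)
    a <- (3 * v_mm3 / (4 * pi * r2 * r3))^(1 / 3)
    semi <- c(a, a * r2, a * r3)
    if (any(shape - 1 - 2 * (max(semi) + margin_mm) < 0))
      stop("tumor (max semi-axis ", round(max(semi), 1), " mm) does not fit in ",
           paste(shape, collapse = "x"), " grid with the required ",
           margin_mm, " mm margin")
    lo <- max(semi) + margin_mm
    center <- sapply(seq_len(3), function(i) runif(1, lo, shape[i] - 1 - lo))

    # random rotation from a random unit quaternion
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
      2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
      2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)
    ), 3, 3, byrow = TRUE)

    # mask on the tumor bounding box only
    rmax <- ceiling(max(semi)) + 1L
    bx <- lapply(seq_len(3), function(i)
      max(0L, floor(center[i] - rmax)):min(shape[i] - 1L, ceiling(center[i] + rmax)))
    g <- as.matrix(expand.grid(x = bx[[1]], y = bx[[2]], z = bx[[3]]))
    d <- sweep(g, 2, center) %*% t(R)
    inside <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 <= 1
    mask <- array(FALSE, shape)
    mask[g[inside, , drop = FALSE] + 1L] <- TRUE
    if (!any(mask)) stop("degenerate tumor: no voxels inside the ellipsoid")

    vox <- array(background_hu + (if (noise_sd_hu > 0)
      rnorm(prod(shape), sd = noise_sd_hu) else 0), shape)

    tumor_val <- tumor_hu_base + mean_shift_hu
    amp <- heterogeneity * noise_sd_hu
    if (amp > 0) {
      # smooth texture on the bounding box, unit SD after blurring
      bdim <- vapply(bx, length, integer(1))
      tex <- .gauss_blur3(array(rnorm(prod(bdim)), bdim), sigma = 3 / 2.355)
      tex <- tex / max(sd(tex), 1e-12)
      full <- array(0, shape)
      full[bx[[1]] + 1L, bx[[2]] + 1L, bx[[3]] + 1L] <- tex * amp
      vox[mask] <- tumor_val + full[mask]
    } else {
      vox[mask] <- tumor_val
    }
    list(volume = ct_volume(vox, spacing = c(1, 1, 1)), mask = mask,
         center = center)
  })
}

# per-case sampling plan: demographics, labels, phantom parameters, seeds.
# Deterministic in config$seed and independent of how cases are realized.
.cohort_plan <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    rng <- config$tumor_volume_range_cc
    sdlog <- 0.45
    meanlog <- log(config$tumor_volume_mean_cc) - sdlog^2 / 2
    vol <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- stats::rlnorm(1, meanlog, sdlog)
        if (v >= rng[1] && v <= rng[2]) { vol[i] <- v; break }
      }
    }
    label <- integer(n)
    label[sample.int(n, config$n_events)] <- 1L
    plan <- data.frame(
      id = sprintf("%s_%03d", config$preset, seq_len(n)),
      cohort = config$preset,
      gender = as.integer(runif(n) < config$male_fraction),
      age = round(runif(n, config$age_range[1], config$age_range[2])),
      tumor_volume_cc = vol,
      cci = sample(seq(config$cci_range[1], config$cci_range[2]), n, replace = TRUE),
      dose_gy = NA_real_, n_fractions = NA_integer_,
      label = label,
      case_seed = sample.int(.Machine$integer.max - 1L, n),
      stringsAsFactors = FALSE
    )
    if (config$preset == "sbrt") {
      scheme <- sample(seq_along(config$dose_schemes), n, replace = TRUE)
      plan$dose_gy <- vapply(scheme, function(s)
        config$dose_schemes[[s]][1] * config$dose_schemes[[s]][2], numeric(1))
      plan$n_fractions <- vapply(scheme, function(s)
        as.integer(config$dose_schemes[[s]][2]), integer(1))
    }
    plan
  })
}

.case_from_plan <- function(plan_row, config) {
  shift <- if (plan_row$label == 1L) config$effect_mean_hu else 0
  het <- if (plan_row$label == 1L) config$effect_texture else 1
  ph <- generate_phantom(shape = config$shape,
                         tumor_volume_cc = plan_row$tumor_volume_cc,
                         heterogeneity = het, mean_shift_hu = shift,
                         seed = plan_row$case_seed,
                         background_hu = config$background_hu,
                         tumor_hu_base = config$tumor_hu_base,
                         noise_sd_hu = config$noise_sd_hu)
  record <- plan_row[setdiff(names(plan_row), "case_seed")]
  list(volume = ph$volume, mask = ph$mask, record = record)
}

#' Generate a phantom cohort
#'
#' Realizes the full cohort described by a [cohort_config()]: exactly
#' `n_subjects` phantoms of which exactly `n_events` carry label 1 and
#' receive the planted effect. Identical seeds yield identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list with `cases` (list of phantom cases, each holding
#'   `volume`, `mask`, `record`) and `manifest` (data.frame, one row per
#'   case).
#' @export
generate_cohort <- function(config) {
  plan <- .cohort_plan(config)
  cases <- lapply(seq_len(nrow(plan)), function(i) .case_from_plan(plan[i, ], config))
  manifest <- plan[setdiff(names(plan), "case_seed")]
  rownames(manifest) <- NULL
  list(cases = cases, manifest = manifest)
}

#' Write a generated cohort to disk
#'
#' Writes one volume and one mask image per case plus the manifest CSV.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param format `"nifti"` (`.nii.gz`) or `"nrrd"`.
#' @return Path of the written manifest CSV.
#' @export
write_cohort <- function(cohort, out_dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  for (case in cohort$cases) {
    id <- case$record$id
    write_volume(case$volume, file.path(out_dir, paste0(id, "_volume", ext)))
    write_volume(ct_volume(array(as.double(case$mask), dim(case$mask)),
                           spacing = case$volume$spacing),
                 file.path(out_dir, paste0(id, "_mask", ext)))
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(cohort$manifest, manifest_path, row.names = FALSE, na = "")
  manifest_path
}
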