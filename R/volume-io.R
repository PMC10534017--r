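# CT volume container, NIfTI/NRRD readers and writers, isotropic
# resampling and cohort manifest loading.
#
# Axis convention: voxel arrays are indexed (x, y, z), 1-based, column-major
# as native R arrays; geometry (spacing, origin) is carried alongside in mm.
# Voxel centers sit at origin + (index - 1) * spacing.

#' CT volume container
#'
#' Bundles a 3D voxel grid in Hounsfield units with its geometry.
#'
#' @param voxels 3D numeric array of HU values, indexed (x, y, z).
#' @param spacing Voxel spacing in mm, length 3, strictly positive.
#' @param origin Physical position (mm) of voxel (1,1,1); default zeros.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("ct_volume requires a 3D array, got ", length(dim(voxels)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      "  HU range: [", round(min(x$voxels), 1), ", ",
      round(max(x$voxels), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Read a CT volume or mask from NIfTI or NRRD
#'
#' The format is auto-detected from the file extension (`.nii`, `.nii.gz`,
#' `.nrrd`). Only 3D images are accepted.
#'
#' @param path Path to the image file.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
    if (length(dim(arr)) != 3L)
      stop("only 3D images are supported; ", path, " has ",
           length(dim(arr)), " dimensions")
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    ct_volume(arr, spacing = abs(pd[1:3]),
              origin = as.numeric(RNifti::origin(img)))
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    r <- read_nrrd(path)
    ct_volume(r$voxels, spacing = r$spacing, origin = r$origin)
  } else {
    stop("unknown volume format (expected .nii, .nii.gz or .nrrd): ", path)
  }
}

#' Write a CT volume to NIfTI or NRRD
#'
#' @param volume A [ct_volume] (or bare 3D array, taken as 1 mm spacing).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "ct_volume")) volume <- ct_volume(volume)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(volume$voxels, path, spacing = volume$spacing,
               origin = volume$origin)
  } else {
    stop("unknown volume format (expected .nii, .nii.gz or .nrrd): ", path)
  }
  invisible(path)
}

#' Resample a volume (and mask) to an isotropic grid
#'
#' The volume is interpolated trilinearly and the mask by nearest neighbour,
#' then re-binarized at 0.5. Output dimensions are chosen so the physical
#' extent is preserved within one voxel.
#'
#' @param volume A [ct_volume].
#' @param mask Optional binary array aligned with `volume`.
#' @param target_mm Target isotropic spacing in mm (default 1).
#' @return A list with `volume` (resampled [ct_volume]) and `mask`
#'   (resampled binary array, or `NULL`).
#' @export
resample_isotropic <- function(volume, mask = NULL, target_mm = 1.0) {
  stopifnot(inherits(volume, "ct_volume"), target_mm > 0)
  sp <- volume$spacing
  din <- dim(volume$voxels)
  if (!is.null(mask) && !identical(dim(mask) * 1L, din * 1L))
    stop("mask grid (", paste(dim(mask), collapse = "x"),
         ") does not match volume grid (", paste(din, collapse = "x"), ")")
  if (all(abs(sp - target_mm) < 1e-9)) {
    return(list(volume = volume, mask = mask))
  }
  dout <- pmax(1L, as.integer(round(din * sp / target_mm)))
  aff <- cbind(diag(target_mm / sp), c(0, 0, 0))
  vox <- .affine_sample(volume$voxels, dout, aff, 0L, 0, TRUE)
  out <- ct_volume(vox, spacing = rep(target_mm, 3), origin = volume$origin)
  mout <- NULL
  if (!is.null(mask)) {
    m <- .affine_sample(array(as.double(mask), din), dout, aff, 1L, 0, TRUE)
    mout <- array(m > 0.5, dout)
    if (!any(mout)) stop("mask is empty after resampling to ", target_mm, " mm")
  }
  list(volume = out, mask = mout)
}

.manifest_columns <- c("id", "cohort", "gender", "age", "tumor_volume_cc",
                       "cci", "dose_gy", "n_fractions", "label")

#' Load a cohort manifest
#'
#' Reads the cohort CSV (one row per patient) and validates its schema:
#' labels must be 0/1, and SBRT rows must carry `dose_gy` and `n_fractions`
#' while surgery rows must leave them empty.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame of patient records with one row per subject.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  if (!all(df$label %in% c(0L, 1L)))
    stop("manifest column 'label' must be 0 or 1; offending row(s): ",
         paste(which(!df$label %in% c(0L, 1L)), collapse = ", "))
  if (!all(df$cohort %in% c("surgery", "sbrt")))
    stop("manifest column 'cohort' must be 'surgery' or 'sbrt'")
  sbrt <- df$cohort == "sbrt"
  for (col in c("dose_gy", "n_fractions")) {
    if (any(sbrt & is.na(df[[col]])))
      stop("sbrt record(s) missing required column '", col, "': rows ",
           paste(which(sbrt & is.na(df[[col]])), collapse = ", "))
  }
  for (col in c("dose_gy", "n_fractions")) {
    if (any(!sbrt & !is.na(df[[col]])))
      stop("surgery record(s) must not carry treatment column '", col, "'")
  }
  df$id <- as.character(df$id)
  df
}
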