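# Minimal NRRD (Nearly Raw Raster Data) reader/writer for 3D scalar grids.
# Covers the subset of the format this package emits and consumes:
# detached headers, per-axis "spacings" or "space directions", raw or
# gzip encoding, little-endian. Written because no NRRD reader ships with
# the installed R stack; the NIfTI path goes through RNifti.

.nrrd_types <- c(
  "double" = 8, "float" = 4, "short" = 2, "int16" = 2, "signed short" = 2,
  "int" = 4, "int32" = 4, "uchar" = 1, "uint8" = 1, "unsigned char" = 1
)

#' Read a 3D NRRD file
#'
#' Supports raw and gzip encodings of scalar 3D grids in little-endian byte
#' order, with geometry taken from `spacings` or diagonal `space directions`.
#'
#' @param path Path to a `.nrrd` file.
#' @return A list with `voxels` (3D array), `spacing` and `origin` (numeric
#'   length-3 vectors, mm).
#' @keywords internal
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  nheader <- nchar(magic, type = "bytes") + 1L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header not terminated by blank line: ", path)
    nheader <- nheader + nchar(line, type = "bytes") + 1L
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- trimws(sub(":=?$", "", kv))
    fields[[tolower(key)]] <- trimws(sub("^[^:]+:=?", "", line))
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (as.integer(fields[["dimension"]]) != 3L || length(dims) != 3L)
    stop("only 3D NRRD volumes are supported (got dimension ",
         fields[["dimension"]], "): ", path)
  type <- fields[["type"]]
  if (!type %in% names(.nrrd_types)) stop("unsupported NRRD type: ", type)
  endian <- fields[["endian"]]
  if (!is.null(endian) && tolower(endian) == "big")
    stop("big-endian NRRD not supported: ", path)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])

  n <- prod(dims)
  size <- .nrrd_types[[type]]
  encoding <- tolower(fields[["encoding"]])
  what <- if (type %in% c("double", "float")) "double" else "integer"
  if (encoding == "raw") {
    data <- readBin(con, what, n = n, size = size, endian = "little")
  } else if (encoding %in% c("gzip", "gz")) {
    blob <- readBin(con, "raw", n = file.size(path) - nheader)
    data <- readBin(memDecompress(blob, type = "gzip"), what, n = n,
                    size = size, endian = "little")
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  list(voxels = array(data, dims), spacing = spacing, origin = origin)
}

#' Write a 3D array as NRRD
#'
#' Emits an attached-header NRRD with raw little-endian `double` data and
#' per-axis spacings.
#'
#' @param voxels 3D numeric array.
#' @param path Output path.
#' @param spacing Voxel spacing in mm (length 3).
#' @param origin Physical origin in mm (length 3).
#' @return `path`, invisibly.
#' @keywords internal
write_nrrd <- function(voxels, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  header <- c(
    "NRRD0004",
    "# generated by mfcrad",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(voxels), collapse = " ")),
    paste("spacings:", paste(format(spacing, scientific = FALSE), collapse = " ")),
    paste0("space origin: (", paste(format(origin, scientific = FALSE), collapse = ","), ")"),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(header, con, sep = "\n")
  writeBin(as.vector(voxels, "double"), con, size = 8, endian = "little")
  invisible(path)
}
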