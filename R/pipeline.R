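# End-to-end pipeline: resolved run configuration (YAML/JSON with full
# defaults and unknown-key rejection), cohort feature extraction, and the
# synth -> radiomics -> deep features -> fuse -> evaluate runner.

#' Default run configuration
#'
#' The nested configuration consumed by [run_pipeline()]; every field has a
#' default, and configuration files may override any subset.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "mfcrad_run",
    cohort = list(preset = "surgery", effect_mean_hu = 0, effect_texture = 1),
    radiomics = list(n_bins = 32L),
    encoder = list(voi_mm = 80L, weights_file = NULL, random_seed = 1L),
    augmentation = list(rotation_deg = 10, scale_range = c(0.9, 1.1),
                        noise_sd = 0.01, multiplicity = 1L),
    fusion = list(corr_threshold = 0.95, test = "wilcox", multiplicity = 4L,
                  noise_fraction = 0.05, balance = TRUE),
    classifiers = list(logistic = list(lambda = 1.0),
                       svm = list(cost = 1.0, tolerance = 1e-3),
                       forest = list(n_trees = 200L, depth = 8L)),
    evaluate = list(variants = c("PI", "R", "DL", "MFC"),
                    classifiers = "logistic",
                    scheme = "mcrv", n_folds = 100L, train_frac = 0.7)
  ), class = "run_config")
}

# recursive merge that rejects keys absent from the defaults
.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- paste0(path, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- .merge_config(base[[key]], override[[key]],
                                   paste0(full, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration file
#'
#' Reads YAML (or JSON) and merges it over [default_run_config()]; unknown
#' keys are rejected before any computation.
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  out <- .merge_config(unclass(cfg), raw)
  class(out) <- "run_config"
  out
}

#' Extract all feature blocks for a synthetic cohort
#'
#' Generates each phantom from the cohort plan, extracts handcrafted and
#' deep features, and discards the volume before moving on, so the full
#' image cohort is never held in memory. The result is identical to
#' generating the cohort with [generate_cohort()] and extracting features
#' case by case.
#'
#' @param config A [cohort_config()].
#' @param weights An `encoder_weights` object (`NULL` skips deep features).
#' @param rconfig A [radiomics_config()].
#' @param econfig An [encoder_config()].
#' @param verbose Print progress.
#' @return A list with `table` (feature table with block tags), `labels`,
#'   `manifest`.
#' @export
synthesize_dataset <- function(config, weights = NULL,
                               rconfig = radiomics_config(),
                               econfig = encoder_config(), verbose = FALSE) {
  plan <- .cohort_plan(config)
  n <- nrow(plan)
  hc <- matrix(NA_real_, n, 105,
               dimnames = list(plan$id, handcrafted_feature_names()))
  dp <- NULL
  if (!is.null(weights)) {
    nd <- utils::tail((attr(weights, "config") %||% econfig)$channels, 1)
    dp <- matrix(NA_real_, n, nd,
                 dimnames = list(plan$id, sprintf("deep__f%03d", seq_len(nd))))
  }
  for (i in seq_len(n)) {
    case <- .case_from_plan(plan[i, ], config)
    hc[i, ] <- extract_handcrafted(case$volume, case$mask, rconfig)
    if (!is.null(weights))
      dp[i, ] <- deep_features(case$volume, case$mask, weights, econfig)
    if (verbose && i %% 10 == 0) message("  case ", i, "/", n)
  }
  manifest <- plan[setdiff(names(plan), "case_seed")]
  table <- assemble_feature_blocks(handcrafted = hc, deep = dp,
                                   clinical = clinical_block(manifest))
  ord <- match(rownames(table), manifest$id)
  list(table = table, labels = manifest$label[ord],
       manifest = manifest[ord, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract feature blocks from volumes on disk
#'
#' Reads each manifest row's volume and mask image (named
#' `<id>_volume.<ext>` / `<id>_mask.<ext>` in `dir`), resamples to 1 mm
#' isotropic, and extracts handcrafted and deep features.
#'
#' @param manifest Data.frame from [load_manifest()].
#' @param dir Directory holding the images.
#' @param weights An `encoder_weights` object (`NULL` skips deep features).
#' @param rconfig,econfig Extraction configurations.
#' @param format `"nifti"` or `"nrrd"`.
#' @return As [synthesize_dataset()].
#' @export
extract_cohort_features <- function(manifest, dir, weights = NULL,
                                    rconfig = radiomics_config(),
                                    econfig = encoder_config(),
                                    format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  n <- nrow(manifest)
  hc <- matrix(NA_real_, n, 105,
               dimnames = list(manifest$id, handcrafted_feature_names()))
  nd <- utils::tail((attr(weights, "config") %||% encoder_config())$channels, 1)
  dp <- if (!is.null(weights))
    matrix(NA_real_, n, nd,
           dimnames = list(manifest$id, sprintf("deep__f%03d", seq_len(nd))))
  for (i in seq_len(n)) {
    id <- manifest$id[i]
    vol <- read_volume(file.path(dir, paste0(id, "_volume", ext)))
    msk <- read_volume(file.path(dir, paste0(id, "_mask", ext)))$voxels > 0.5
    rs <- resample_isotropic(vol, msk, 1.0)
    hc[i, ] <- extract_handcrafted(rs$volume, rs$mask, rconfig)
    if (!is.null(weights))
      dp[i, ] <- deep_features(rs$volume, rs$mask, weights, econfig)
  }
  table <- assemble_feature_blocks(handcrafted = hc, deep = dp,
                                   clinical = clinical_block(manifest))
  ord <- match(rownames(table), manifest$id)
  list(table = table, labels = manifest$label[ord],
       manifest = manifest[ord, ])
}

#' Run the full pipeline
#'
#' Synthesizes (or loads) a cohort, extracts handcrafted and deep feature
#' blocks, fuses them with the clinical covariates, evaluates the requested
#' model variants and classifiers under the configured validation scheme,
#' and writes result tables, the ROC figure and a run log.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [load_run_config()].
#' @param cohort_dir Optional directory of an existing written cohort
#'   (with manifest.csv); when `NULL` the synthetic cohort configured in
#'   `config$cohort` is generated.
#' @return Invisible list with `results`, `report` paths and the resolved
#'   config.
#' @export
run_pipeline <- function(config = default_run_config(), cohort_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  econfig <- encoder_config(voi_mm = config$encoder$voi_mm)
  weights <- load_pretrained(config$encoder$weights_file, econfig,
                             seed = config$encoder$random_seed)
  rconfig <- radiomics_config(n_bins = config$radiomics$n_bins)

  if (is.null(cohort_dir)) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
    ds <- synthesize_dataset(cc, weights, rconfig, econfig)
  } else {
    manifest <- load_manifest(file.path(cohort_dir, "manifest.csv"))
    ds <- extract_cohort_features(manifest, cohort_dir, weights, rconfig,
                                  econfig)
  }
  utils::write.csv(cbind(id = rownames(ds$table), ds$table),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  fus <- do.call(fusion_config, config$fusion)
  ev <- config$evaluate
  results <- list()
  for (v in ev$variants) {
    clfs <- if (v == "DL") "head" else ev$classifiers
    for (cl in clfs) {
      spec <- if (cl == "head") classifier_spec() else
        do.call(classifier_spec, c(list(kind = cl),
                                   config$classifiers[[cl]]))
      variant <- model_variant(v, classifier = spec)
      abbrev <- c(logistic = "LR", svm = "SVM", forest = "RF")
      label <- if (v == "DL") "DL" else paste0(v, " (", abbrev[[cl]], ")")
      results[[label]] <- if (ev$scheme == "loocv")
        run_loocv(ds$table, ds$labels, variant, fus, seed = config$seed)
      else
        run_mcrv(ds$table, ds$labels, variant, n_folds = ev$n_folds,
                 seed = config$seed, config = fus,
                 train_frac = ev$train_frac)
    }
  }
  report <- render_report(results, out_dir)
  log <- list(package_version = as.character(utils::packageVersion("mfcrad")),
              config = unclass(config),
              fold_seed_rule = "fold_seed = seed + fold_index",
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(results = results, report = report, config = config))
}
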