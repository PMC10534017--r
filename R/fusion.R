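# Feature-table assembly and the preprocessing chain applied inside every
# training fold: z-score normalization from training statistics, Gaussian
# noise oversampling of training rows, and multicollinearity reduction by
# connected components of the |r| > threshold graph with univariate-p
# representative selection.

#' Fusion / preprocessing configuration
#'
#' @param corr_threshold Absolute Pearson correlation above which two
#'   features are considered redundant (default 0.95).
#' @param test Univariate two-group test used to pick each subset's
#'   representative: `"wilcox"` (Mann-Whitney, default) or `"t"` (Welch).
#' @param multiplicity Oversampling replication factor per training row.
#' @param noise_fraction Oversampling noise SD as a fraction of each
#'   feature's training SD.
#' @param balance Replicate the minority class to parity before
#'   oversampling.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(corr_threshold = 0.95, test = c("wilcox", "t"),
                          multiplicity = 4L, noise_fraction = 0.05,
                          balance = TRUE) {
  test <- match.arg(test)
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("corr_threshold must be in (0, 1)")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  structure(list(corr_threshold = corr_threshold, test = test,
                 multiplicity = as.integer(multiplicity),
                 noise_fraction = noise_fraction, balance = balance),
            class = "fusion_config")
}

#' Assemble the multi-block feature table
#'
#' Concatenates the handcrafted, deep and clinical blocks (in that order)
#' into one table, checking patient-id alignment. The clinical block holds
#' gender, age, tumor volume and comorbidity index, plus prescription dose
#' and fraction count for SBRT cohorts (4 or 6 columns).
#'
#' @param handcrafted,deep Numeric matrices/data.frames with patient ids as
#'   row names (may be `NULL` to omit a block).
#' @param clinical Data.frame of clinical covariates with patient ids as
#'   row names.
#' @return A data.frame with a `blocks` attribute naming each column's
#'   block (`handcrafted`, `deep`, `clinical`).
#' @export
assemble_feature_blocks <- function(handcrafted = NULL, deep = NULL,
                                    clinical = NULL) {
  blocks <- list(handcrafted = handcrafted, deep = deep, clinical = clinical)
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("no feature blocks supplied")
  ids <- lapply(blocks, rownames)
  if (any(vapply(ids, is.null, logical(1))))
    stop("every block needs patient ids as row names")
  ref <- sort(ids[[1]])
  for (b in names(blocks)) {
    if (!identical(sort(ids[[b]]), ref)) {
      bad <- c(setdiff(ids[[b]], ref), setdiff(ref, ids[[b]]))
      stop("patient ids differ between blocks; offending id(s): ",
           paste(unique(bad), collapse = ", "))
    }
  }
  parts <- lapply(blocks, function(b) as.data.frame(b)[ref, , drop = FALSE])
  out <- do.call(cbind, unname(parts))
  if (anyDuplicated(names(out)))
    stop("duplicate column names across blocks: ",
         paste(names(out)[duplicated(names(out))], collapse = ", "))
  rownames(out) <- ref
  attr(out, "blocks") <- rep(names(blocks), vapply(parts, ncol, integer(1)))
  names(attr(out, "blocks")) <- names(out)
  out
}

#' Build the clinical covariate block from a manifest
#'
#' @param manifest Data.frame as returned by [load_manifest()] or
#'   [generate_cohort()].
#' @return Data.frame with ids as row names; 4 columns for surgery cohorts,
#'   6 (adding `dose_gy`, `n_fractions`) for SBRT.
#' @export
clinical_block <- function(manifest) {
  cols <- c("gender", "age", "tumor_volume_cc", "cci")
  if (all(manifest$cohort == "sbrt")) cols <- c(cols, "dose_gy", "n_fractions")
  out <- manifest[, cols, drop = FALSE]
  out[] <- lapply(out, as.numeric)
  rownames(out) <- manifest$id
  out
}

#' Z-score normalization from training statistics
#'
#' Centers and scales every feature by its training-set mean and SD;
#' held-out rows are transformed with the training statistics only.
#' Zero-variance training features map to 0 and are flagged.
#'
#' @param train_table Numeric matrix/data.frame of training rows.
#' @param apply_table Optional rows to transform with the fitted
#'   statistics.
#' @return List with `train`, `apply` (or `NULL`), `center`, `scale` and
#'   `constant` (logical flag per feature).
#' @export
zscore_normalize <- function(train_table, apply_table = NULL) {
  X <- as.matrix(train_table)
  if (!nrow(X)) stop("empty training table")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  constant <- !is.finite(scl) | scl == 0
  scl[constant] <- 1
  tr <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  tr[, constant] <- 0
  ap <- NULL
  if (!is.null(apply_table)) {
    A <- as.matrix(apply_table)
    ap <- sweep(sweep(A, 2, ctr), 2, scl, `/`)
    ap[, constant] <- 0
  }
  list(train = tr, apply = ap, center = ctr, scale = scl, constant = constant)
}

#' Gaussian-noise oversampling of training rows
#'
#' Optionally balances classes by replicating minority rows to parity, then
#' replicates every row `multiplicity` times; the first copy is exact and
#' the rest receive independent per-feature noise
#' `N(0, (noise_fraction * sd_j)^2)` where `sd_j` is the original training
#' SD of feature `j`. Never applied to held-out rows.
#'
#' @param train_table Numeric matrix/data.frame of training rows.
#' @param labels Binary labels aligned with the rows.
#' @param config A [fusion_config()].
#' @param seed Integer seed.
#' @return List with `table` (matrix) and `labels`.
#' @export
gaussian_oversample <- function(train_table, labels, config = fusion_config(),
                                seed = 1L) {
  X <- as.matrix(train_table)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  sds <- apply(X, 2, sd)
  sds[!is.finite(sds)] <- 0
  with_seed(seed, {
    if (config$balance && length(unique(labels)) == 2L) {
      tab <- table(labels)
      minority <- as.integer(names(tab)[which.min(tab)])
      need <- max(tab) - min(tab)
      if (need > 0) {
        pool <- which(labels == minority)
        extra <- pool[((seq_len(need) - 1L) %% length(pool)) + 1L]
        X <- rbind(X, X[extra, , drop = FALSE])
        labels <- c(labels, labels[extra])
      }
    }
    k <- config$multiplicity
    n <- nrow(X)
    out <- X[rep(seq_len(n), each = k), , drop = FALSE]
    out_labels <- labels[rep(seq_len(n), each = k)]
    if (k > 1 && config$noise_fraction > 0) {
      noisy <- rep(seq_len(k), times = n) != 1L
      nn <- sum(noisy)
      noise <- matrix(rnorm(nn * ncol(X)), nn, ncol(X))
      noise <- sweep(noise, 2, config$noise_fraction * sds, `*`)
      out[noisy, ] <- out[noisy, , drop = FALSE] + noise
    }
    rownames(out) <- NULL
    list(table = out, labels = out_labels)
  })
}

# univariate two-group p-value per feature column
.univariate_p <- function(X, labels, test) {
  g1 <- labels == 1L
  apply(X, 2, function(x) {
    if (length(unique(x)) < 2L) return(1)
    p <- tryCatch(
      if (test == "t") t.test(x[g1], x[!g1])$p.value
      else wilcox.test(x[g1], x[!g1], exact = FALSE)$p.value,
      error = function(e) 1)
    if (is.finite(p)) p else 1
  })
}

#' Multicollinearity reduction
#'
#' Builds a graph on features with an edge where `|Pearson r| >
#' corr_threshold`; each connected component forms a redundant subset, from
#' which the single feature with the smallest univariate two-group p-value
#' against the outcome is kept (ties broken by the earliest column).
#' Constant features have undefined correlation; they are kept and flagged.
#'
#' @param table Numeric matrix/data.frame (rows = patients).
#' @param labels Binary outcome labels.
#' @param config A [fusion_config()].
#' @return List with `keep` (column names in stable input order),
#'   `subsets` (list of component memberships), `p_values` and
#'   `constant_features`.
#' @export
multicollinearity_reduce <- function(table, labels, config = fusion_config()) {
  X <- as.matrix(table)
  if (nrow(X) < 2L) stop("need at least 2 rows to assess collinearity")
  labels <- as.integer(labels)
  sds <- apply(X, 2, sd)
  constant <- !is.finite(sds) | sds == 0
  nm <- colnames(X)
  if (is.null(nm)) nm <- colnames(X) <- paste0("f", seq_len(ncol(X)))

  keep <- nm[constant]
  subsets <- list()
  pvals <- setNames(rep(NA_real_, ncol(X)), nm)
  var_idx <- which(!constant)
  if (length(var_idx)) {
    C <- abs(suppressWarnings(cor(X[, var_idx, drop = FALSE])))
    C[!is.finite(C)] <- 0
    adj <- C > config$corr_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    pvals[var_idx] <- .univariate_p(X[, var_idx, drop = FALSE], labels,
                                    config$test)
    for (cc in unique(comp)) {
      members <- var_idx[comp == cc]
      if (length(members) == 1L) {
        keep <- c(keep, nm[members])
      } else {
        best <- members[which.min(pvals[members])]
        keep <- c(keep, nm[best])
        subsets <- c(subsets, list(nm[members]))
      }
    }
  }
  keep <- nm[nm %in% keep]               # stable original order
  list(keep = keep, subsets = subsets, p_values = pvals,
       constant_features = nm[constant])
}
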