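# Independent brute-force oracles used to validate the texture-matrix
# builders and the ROC/AUC implementation. These deliberately use different
# algorithms from the package code: exhaustive pair enumeration (GLCM),
# grid-line extraction with run-length encoding (GLRLM), queue-based
# flood fill (GLSZM), and all-pairs concordance counting (AUC).

oracle_glcm <- function(bins, ng, offset) {
  d <- dim(bins)
  M <- matrix(0L, ng, ng)
  idx <- which(bins > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    q <- p + offset
    if (any(q < 1) || any(q > d)) next
    g2 <- bins[q[1], q[2], q[3]]
    if (g2 == 0) next
    g1 <- bins[p[1], p[2], p[3]]
    M[g1, g2] <- M[g1, g2] + 1L
    M[g2, g1] <- M[g2, g1] + 1L
  }
  M
}

oracle_glrlm <- function(bins, ng, offset) {
  d <- dim(bins)
  maxlen <- max(d)
  R <- matrix(0L, ng, maxlen)
  # line starts: grid voxels whose predecessor along -offset is off-grid
  all_idx <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  pred <- sweep(all_idx, 2, offset)
  starts <- all_idx[apply(pred, 1, function(p) any(p < 1) || any(p > d)), ,
                    drop = FALSE]
  for (r in seq_len(nrow(starts))) {
    p <- starts[r, ]
    vals <- integer(0)
    while (all(p >= 1) && all(p <= d)) {
      vals <- c(vals, bins[p[1], p[2], p[3]])
      p <- p + offset
    }
    runs <- rle(vals)
    for (k in seq_along(runs$values)) {
      g <- runs$values[k]
      if (g > 0) R[g, runs$lengths[k]] <- R[g, runs$lengths[k]] + 1L
    }
  }
  R
}

oracle_glszm <- function(bins, ng) {
  d <- dim(bins)
  visited <- array(FALSE, d)
  sizes <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(bins > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    p0 <- idx_all[r, ]
    if (visited[p0[1], p0[2], p0[3]]) next
    g <- bins[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    visited[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!visited[q[1], q[2], q[3]] && bins[q[1], q[2], q[3]] == g) {
          visited[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    sizes[[length(sizes) + 1L]] <- c(g, size)
  }
  maxs <- max(vapply(sizes, `[`, integer(1), 2))
  S <- matrix(0L, ng, maxs)
  for (z in sizes) S[z[1], z[2]] <- S[z[1], z[2]] + 1L
  S
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# random small discretized ROI as used by the oracle-equivalence suites
random_droi <- function(ng = 4, maxdim = 5) {
  d <- sample(2:maxdim, 3, replace = TRUE)
  bins <- array(sample(0:ng, prod(d), replace = TRUE), d)
  if (!any(bins > 0)) bins[1, 1, 1] <- 1L
  structure(list(bins = bins, n_bins = as.integer(ng),
                 n_voxels = sum(bins > 0)), class = "droi")
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# small fast phantom for feature-level tests
tiny_phantom <- function(seed = 1, cc = 1.0, het = 1, shift = 0) {
  generate_phantom(c(48L, 48L, 48L), tumor_volume_cc = cc,
                   heterogeneity = het, mean_shift_hu = shift, seed = seed)
}
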