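test_that("family feature vectors have the advertised lengths", {
  droi <- random_droi(4, 5)
  expect_length(texture_features(compute_glcm(droi), "glcm"), 22)
  expect_length(texture_features(compute_glrlm(droi), "glrlm"), 16)
  expect_length(texture_features(compute_glszm(droi), "glszm"), 16)
})

test_that("uniform ROI yields zero GLCM contrast and pure diagonal stats", {
  droi <- discretize_fbn(array(3, c(4, 4, 4)), array(TRUE, c(4, 4, 4)), 32)
  f <- texture_features(compute_glcm(droi), "glcm")
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["angular_second_moment"]), 1)
  expect_equal(unname(f["joint_entropy"]), 0)
})

test_that("short-run emphasis on the 1x1x4 worked example is 0.25", {
  # bins [1,1,2,2] along (0,0,1): runs R[1,2]=1, R[2,2]=1;
  # SRE = (1/4 + 1/4) / 2 = 0.25
  bins <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  droi <- structure(list(bins = bins, n_bins = 2L, n_voxels = 4L),
                    class = "droi")
  m <- compute_glrlm(droi)$directional[[3]]
  f <- texture_features(m, "glrlm", n_voxels = 4)
  expect_equal(unname(f["short_run_emphasis"]), 0.25)
  expect_equal(unname(f["run_percentage"]), 0.5)
})

test_that("first-order features handle constants, two-bin splits and means", {
  const <- array(12, c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  fo <- first_order_features(const, mask)
  expect_equal(unname(fo$intensity["variance"]), 0)
  expect_equal(unname(fo$histogram["entropy"]), 0)

  # even two-bin split: entropy = 1 bit
  arr <- array(rep(c(0, 10), each = 4), c(8, 1, 1))
  fo2 <- first_order_features(arr, array(TRUE, c(8, 1, 1)), n_bins = 32)
  expect_equal(unname(fo2$histogram["entropy"]), 1)

  arr3 <- array(c(-10, 10, 30), c(3, 1, 1))
  fo3 <- first_order_features(arr3, array(TRUE, c(3, 1, 1)))
  expect_equal(unname(fo3$intensity["mean"]), 10)
  expect_length(fo3$intensity, 18)
  expect_length(fo3$histogram, 20)
})

test_that("cube shape features match the voxel-face oracle", {
  mask <- array(FALSE, c(20, 20, 20))
  mask[6:15, 6:15, 6:15] <- TRUE  # 10x10x10 voxels at 1 mm
  f <- shape_features(mask, c(1, 1, 1))
  expect_equal(unname(f["volume_mm3"]), 1000)
  expect_equal(unname(f["surface_area_mm2"]), 600)
  expect_equal(unname(f["surface_to_volume_ratio"]), 0.6)
  # isotropic cube: principal axes equal
  expect_equal(unname(f["elongation"]), 1)
  expect_equal(unname(f["flatness"]), 1)
  expect_equal(unname(f["maximum_3d_diameter_mm"]), sqrt(3 * 81),
               tolerance = 1e-9)
})

test_that("shape features are invariant to 90-degree rotation and near-invariant for spheres", {
  # digital sphere
  d <- c(30, 30, 30)
  ctr <- c(15.5, 14.5, 15.2)
  g <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  mask <- array(colSums((t(g) - ctr)^2) <= 8^2, d)
  f1 <- shape_features(mask, c(1, 1, 1))
  f2 <- shape_features(aperm(mask[, , d[3]:1], c(1, 3, 2)), c(1, 1, 1))
  expect_equal(f1[["volume_mm3"]], f2[["volume_mm3"]])
  expect_equal(f1[["surface_area_mm2"]], f2[["surface_area_mm2"]])
  expect_equal(unname(f1["sphericity"]), unname(f2["sphericity"]),
               tolerance = 0.02)
  # sphericity of a digital sphere with voxel-face surface is bounded
  expect_gt(f1[["sphericity"]], 0.5)
  expect_lt(f1[["sphericity"]], 1.1)
})

test_that("the full handcrafted vector is 105 long, tagged, finite and deterministic", {
  ph <- tiny_phantom(seed = 3)
  f1 <- extract_handcrafted(ph$volume, ph$mask)
  f2 <- extract_handcrafted(ph$volume, ph$mask)
  expect_length(f1, 105)
  expect_identical(names(f1), handcrafted_feature_names())
  expect_true(all(is.finite(f1)))
  expect_identical(f1, f2)
  fam <- table(attr(f1, "families"))
  expect_equal(as.integer(fam[c("shape", "intensity", "histogram",
                                "glcm", "glrlm", "glszm")]),
               c(13L, 18L, 20L, 22L, 16L, 16L))
})

test_that("translation leaves all 105 features unchanged", {
  ph <- tiny_phantom(seed = 4)
  f1 <- extract_handcrafted(ph$volume, ph$mask)
  shift <- c(3L, -2L, 4L)
  d <- dim(ph$mask)
  tr <- function(a, fillv) {
    out <- array(fillv, d)
    src <- list(1:(d[1] - 3), 3:d[2], 1:(d[3] - 4))
    dst <- list(4:d[1], 1:(d[2] - 2), 5:d[3])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  vol2 <- ct_volume(tr(ph$volume$voxels, -800), spacing = c(1, 1, 1))
  mask2 <- tr(ph$mask, FALSE)
  f2 <- extract_handcrafted(vol2, mask2)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-9)
})

test_that("features stay finite on minimal ROIs", {
  # two voxels, two intensities
  arr <- array(c(0, 100, rep(0, 25)), c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3)); mask[1:2, 1, 1] <- TRUE
  f <- extract_handcrafted(arr, mask)
  expect_true(all(is.finite(f)))
  # single voxel: degenerate texture conventions kick in
  mask1 <- array(FALSE, c(3, 3, 3)); mask1[2, 2, 2] <- TRUE
  f1 <- extract_handcrafted(arr, mask1)
  expect_true(all(is.finite(f1)))
  expect_true(isTRUE(attr(f1, "degenerate_roi")))
})
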