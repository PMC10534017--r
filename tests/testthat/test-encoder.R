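test_that("VOI cropping centers the tumor and pads outside the scan", {
  dims <- c(100, 100, 100)
  vox <- array(0, dims)
  mask <- array(FALSE, dims)
  # tumor centered at (50, 50, 50): central 80-cube is fully inside
  mask[46:54, 46:54, 46:54] <- TRUE
  vox[mask] <- 100
  blk <- crop_voi(vox, mask, 80)
  expect_identical(dim(blk), c(80L, 80L, 80L))
  expect_identical(blk, vox[11:90, 11:90, 11:90])
  # mask centroid inside the crop sits within 1 voxel of the crop center
  mblk <- crop_voi(array(as.double(mask), dims), mask, 80) > 0.5
  ctr <- colMeans(which(mblk, arr.ind = TRUE))
  expect_true(all(abs(ctr - c(40.5, 40.5, 40.5)) <= 1))
})

test_that("cropping near a face pads with air", {
  dims <- c(100, 100, 100)
  vox <- array(50, dims)
  mask <- array(FALSE, dims)
  mask[8:12, 48:52, 48:52] <- TRUE  # centroid 10 voxels from the x face
  blk <- crop_voi(vox, mask, 80)
  # crop extends 40 voxels below a centroid 10 voxels from the face:
  # 40 - 10 = 30 one-voxel slabs fall outside the scan
  n_padded <- sum(blk == -1000)
  expect_equal(n_padded, 30 * 80 * 80)
  expect_true(all(blk %in% c(-1000, 50)))
  # a GTV wider than the VOI is refused
  big <- array(FALSE, dims); big[5:95, 48:52, 48:52] <- TRUE
  expect_error(crop_voi(vox, big, 80), "VOI")
})

test_that("input normalization maps the HU window onto [0, 1]", {
  expect_equal(normalize_input(array(c(-1000, 0, 1000, -1500, 2500), c(5, 1, 1))),
               array(c(0, 0.5, 1, 0, 1), c(5, 1, 1)))
})

test_that("augmentation returns the original first and is seed-deterministic", {
  blk <- array(runif(16^3), c(16, 16, 16))
  spec <- augmentation_spec(multiplicity = 3L)
  a1 <- augment_3d(blk, spec, seed = 5)
  a2 <- augment_3d(blk, spec, seed = 5)
  expect_length(a1, 3)
  expect_identical(a1[[1]], blk)
  expect_identical(a1[[2]], a2[[2]])
  expect_false(identical(a1[[2]], a1[[3]]))

  # identity spec: all copies equal the input
  id <- augmentation_spec(rotation_deg = 0, scale_range = c(1, 1),
                          flip_axes = integer(0), noise_sd = 0,
                          multiplicity = 3L)
  ai <- augment_3d(blk, id, seed = 1)
  expect_equal(ai[[2]], blk)
  expect_equal(ai[[3]], blk)
  expect_error(augmentation_spec(multiplicity = 0), "multiplicity")
})

test_that("encoder halves the grid four times and ends at 512 channels", {
  w <- init_encoder_weights(seed = 1)
  blk <- array(runif(32^3), c(32, 32, 32))
  out <- encode_deep_features(blk, w, return_map = TRUE)
  expect_length(out$features, 512)
  expect_identical(dim(out$map), c(512L, 2L, 2L, 2L))  # 32 / 2^4
  expect_true(all(is.finite(out$features)))
  expect_error(encode_deep_features(array(0, c(30, 30, 30)), w), "divisible")
})

test_that("zero weights force a zero encoding and seeds are reproducible", {
  w <- init_encoder_weights(seed = 1)
  for (nm in names(w)) {
    w[[nm]]$weight[] <- 0
    w[[nm]]$bias[] <- 0
  }
  blk <- array(runif(16^3), c(16, 16, 16))
  expect_true(all(encode_deep_features(blk, w) == 0))

  w1 <- init_encoder_weights(seed = 9)
  w2 <- init_encoder_weights(seed = 9)
  expect_identical(w1[["block3_conv2"]]$weight, w2[["block3_conv2"]]$weight)
  f1 <- encode_deep_features(blk, w1)
  f2 <- encode_deep_features(blk, w2)
  expect_identical(f1, f2)
  w3 <- init_encoder_weights(seed = 10)
  expect_false(identical(encode_deep_features(blk, w3), f1))
})

test_that("global average pooling is invariant to spatial permutation of the final map", {
  w <- init_encoder_weights(seed = 2)
  blk <- array(runif(16^3), c(16, 16, 16))
  out <- encode_deep_features(blk, w, return_map = TRUE)
  m <- out$map
  d <- dim(m)
  perm <- array(m[, d[2]:1, , , drop = FALSE], d)  # flip one spatial axis
  gap_perm <- rowMeans(matrix(perm, nrow = d[1]))
  expect_equal(unname(out$features), gap_perm)
})

test_that("weight archives load back, and mismatches name the tensor", {
  w <- init_encoder_weights(seed = 3)
  p <- withr::local_tempfile(fileext = ".rds")
  save_encoder_weights(w, p)
  back <- load_pretrained(p)
  expect_identical(back[["block1_conv1"]]$weight, w[["block1_conv1"]]$weight)

  trunc <- unclass(w)
  trunc[["block5_conv2"]] <- NULL
  saveRDS(trunc, p)
  expect_error(load_pretrained(p), "block5_conv2")

  bad <- unclass(w)
  bad[["block2_conv1"]]$weight <- bad[["block2_conv1"]]$weight[1:10, , , , ,
                                                               drop = FALSE]
  saveRDS(bad, p)
  expect_error(load_pretrained(p), "block2_conv1")

  # absent file + seed falls back to reproducible random weights
  r1 <- load_pretrained(NULL, seed = 4)
  r2 <- load_pretrained(NULL, seed = 4)
  expect_identical(r1[["block1_conv2"]]$weight, r2[["block1_conv2"]]$weight)
  blk <- array(runif(16^3), c(16, 16, 16))
  expect_false(identical(encode_deep_features(blk, back),
                         encode_deep_features(blk, r1)))
})
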