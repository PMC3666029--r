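test_that("loading stacks masked voxels in raster order", {
  set.seed(101)
  dims <- c(4, 4, 4)
  v1 <- array(rnorm(64), dims)
  v2 <- array(rnorm(64), dims)
  mask <- array(0, dims)
  mask[sample(64, 10)] <- 1
  paths <- c(write_test_volume(v1), write_test_volume(v2))
  fm <- load_feature_maps(paths, write_test_volume(mask), "ALFF")
  expect_equal(dim(fm$data), c(2L, 10L))
  keep <- which(mask != 0)   # linear order == raster order
  expect_equal(fm$data[1, ], v1[keep], tolerance = 1e-6)
  expect_equal(fm$data[2, ], v2[keep], tolerance = 1e-6)
})

test_that("non-finite voxels inside the mask and empty masks are rejected", {
  dims <- c(3, 3, 3)
  bad <- array(1, dims); bad[2, 2, 2] <- NaN
  mask <- array(1, dims)
  p_bad <- write_test_volume(bad)
  expect_error(load_feature_maps(p_bad, write_test_volume(mask), "FA"),
               "non-finite")
  empty <- array(0, dims)
  expect_error(
    load_feature_maps(p_bad, write_test_volume(empty), "FA"),
    "empty")
  small <- write_test_volume(array(1, c(2, 2, 2)))
  expect_error(load_feature_maps(small, write_test_volume(mask), "FA"),
               "grid")
})

test_that("normalization hits the target mean square and preserves ratios", {
  m1 <- feature_matrix(matrix(2, 4, 5), "a")          # msq 4
  m2 <- feature_matrix(matrix(c(1, -1) / 2, 4, 5), "b")  # msq 0.25
  res <- normalize_modalities(list(m1, m2), target_msq = 1)
  expect_equal(res$records$factor, c(0.5, 2))
  expect_equal(res$records$post_msq, c(1, 1), tolerance = 1e-10)
  expect_true(all(res$mats[[1]]$data == 1))
  # within-modality ratios unchanged
  r_before <- m2$data[1, 2] / m2$data[2, 1]
  r_after <- res$mats[[2]]$data[1, 2] / res$mats[[2]]$data[2, 1]
  expect_equal(r_after, r_before)
  # identity case: already at target
  m3 <- feature_matrix(matrix(c(1, -1), 4, 6), "c")
  res3 <- normalize_modalities(list(m3))
  expect_identical(res3$mats[[1]]$data, m3$data)
  expect_equal(res3$records$factor, 1)
  expect_error(normalize_modalities(list(feature_matrix(matrix(1e-30 * 0,
                                                               3, 3), "z"))),
               "zeros")
})

test_that("normalization is idempotent and commutes with subject order", {
  set.seed(7)
  m <- feature_matrix(matrix(rnorm(60, sd = 3), 6, 10), "a",
                      subject_ids = letters[1:6])
  once <- normalize_modalities(list(m))$mats[[1]]
  twice <- normalize_modalities(list(once))$mats[[1]]
  expect_equal(twice$data, once$data, tolerance = 1e-10)

  perm <- c(3, 1, 2, 6, 5, 4)
  mp <- feature_matrix(m$data[perm, ], "a", subject_ids = letters[perm])
  np <- normalize_modalities(list(mp))$mats[[1]]
  expect_equal(np$data, once$data[perm, ], tolerance = 1e-12)
})

test_that("component maps round-trip through NIfTI", {
  set.seed(8)
  dims <- c(5, 4, 3)
  coords <- arrayInd(sample(prod(dims), 12), dims)
  coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), ]
  maps <- matrix(rnorm(24), 2, 12)
  prefix <- tempfile()
  paths <- save_component_maps(maps, coords, dims, diag(4), prefix)
  expect_length(paths, 2)
  vol <- RNifti::readNifti(paths[1])
  arr <- array(as.numeric(vol), dims)
  expect_equal(arr[coords], maps[1, ], tolerance = 1e-6)
  outside <- array(TRUE, dims); outside[coords] <- FALSE
  expect_true(all(arr[outside] == 0))
  # all-zero component stays zero; width mismatch errors
  p0 <- save_component_maps(matrix(0, 1, 12), coords, dims, diag(4),
                            tempfile())
  expect_true(all(as.numeric(RNifti::readNifti(p0[1])) == 0))
  expect_error(save_component_maps(matrix(0, 1, 5), coords, dims, diag(4),
                                   tempfile()),
               "mask")
})

test_that("feature_matrix validates its invariants", {
  expect_error(feature_matrix(matrix(c(1, NA, 3, 4), 2, 2), "a"),
               "non-finite")
  expect_error(feature_matrix(matrix(1:4, 1, 4), "a"), "2 subjects")
  expect_error(feature_matrix(matrix(1:4, 2, 2), "a",
                              mask_coords = rbind(c(1, 1, 1), c(1, 1, 1)),
                              grid_shape = c(2, 1, 1)),
               "duplicate")
  expect_error(feature_matrix(matrix(1:4, 2, 2), "a",
                              subject_ids = c("s", "s")),
               "unique")
})
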