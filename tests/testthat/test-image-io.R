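test_that("volume geometry comes from the affine", {
  v <- volume_image(array(0, c(10, 10, 10)))
  expect_equal(voxel_size(v), c(1, 1, 1))
  v2 <- volume_image(array(0, c(4, 4, 4)), affine = diag(c(2, 2, 2, 1)))
  expect_equal(voxel_size(v2), c(2, 2, 2))
  expect_error(volume_image(array(0, c(4, 4))), "3D")
  bad <- diag(c(1, 1, 0, 1))
  expect_error(volume_image(array(0, c(4, 4, 4)), affine = bad),
               "invertible")
})

test_that("NIfTI round-trip preserves masks exactly and floats to 1e-6", {
  set.seed(42)
  aff <- diag(c(1, 1, 2, 1)); aff[1:3, 4] <- c(-12, -13, -14)
  m <- binary_mask(array(runif(6 * 5 * 4) > 0.5, c(6, 5, 4)), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  m2 <- read_mask(f)
  expect_identical(m2$data, m$data)
  expect_equal(voxel_count(m2), voxel_count(m))
  expect_lt(max(abs(m2$affine - m$affine)), 1e-6)
  expect_equal(voxel_size(m2), c(1, 1, 2))

  v <- volume_image(array(rnorm(6 * 5 * 4), c(6, 5, 4)), affine = aff)
  fv <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, fv)
  v2 <- read_volume(fv)
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
})

test_that("4D files and bad paths are rejected", {
  a4 <- RNifti::asNifti(array(0, c(4, 4, 4, 3)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(a4, f)
  expect_error(read_volume(f), "expected 3D")
  # trailing singleton axes are squeezed, not rejected
  a1 <- RNifti::asNifti(array(1, c(4, 4, 4, 1)))
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(a1, f1)
  expect_equal(dim(read_volume(f1)$data), c(4, 4, 4))
  expect_error(read_volume(tempfile()), "not found")
  v <- volume_image(array(0, c(4, 4, 4)))
  expect_error(write_volume(v, file.path(tempfile(), "x.nii.gz")),
               "directory")
})

test_that("binarize uses strict inequality and is idempotent", {
  z <- volume_image(array(0, c(5, 5, 5)))
  expect_equal(voxel_count(binarize(z, 0.5)), 0)
  v <- volume_image(array(rep(c(0, 1, 2), 9), c(3, 3, 3)))
  expect_equal(voxel_count(binarize(v, 0.5)), 18)
  half <- volume_image(array(0.5, c(4, 4, 4)))
  expect_equal(voxel_count(binarize(half, 0.5)), 0)
  set.seed(7)
  for (thr in c(0.1, 0.5, 0.9)) {
    m <- rand_mask(c(8L, 8L, 8L))
    m2 <- binarize(binarize(volume_image(m$data + 0, m$affine), thr), thr)
    expect_identical(m2$data, binarize(volume_image(m$data + 0, m$affine),
                                       thr)$data)
    expect_identical(binarize(m, thr)$data, m$data)
  }
})

test_that("non-binary mask files are binarized at 0.5 with a warning", {
  v <- volume_image(array(c(0, 0.2, 0.7, 1), c(4, 4, 4)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  expect_warning(m <- read_mask(f), "non-binary")
  expect_equal(voxel_count(m), 32)   # 0.7 and 1 survive
})

test_that("common-space validation reports shape and affine mismatches", {
  a <- volume_image(array(0, c(8, 8, 8)))
  chp <- array(0L, c(8, 8, 8)); chp[4, 4, 4] <- 1L
  ok <- subject_bundle("s1", list(T1w = a),
                       list(T1w = list(r1 = binary_mask(chp))),
                       binary_mask(array(1L, c(8, 8, 8))))
  expect_s3_class(ok, "subject_bundle")

  b_badshape <- list(subject_id = "s2", intensities = list(T1w = a),
                     chp_masks = list(),
                     ventricle_mask = binary_mask(array(1L, c(9, 8, 8))),
                     truth_mask = NULL)
  rep <- validate_common_space(b_badshape)
  expect_false(rep$pass)
  expect_match(rep$mismatches, "ventricles.*shape")

  aff <- diag(4); aff[1, 4] <- 1e-9
  b_tol <- list(subject_id = "s3", intensities = list(T1w = a),
                chp_masks = list(),
                ventricle_mask = binary_mask(array(1L, c(8, 8, 8)),
                                             affine = aff),
                truth_mask = NULL)
  expect_true(validate_common_space(b_tol, tol = 1e-6)$pass)
  aff2 <- diag(4); aff2[1, 4] <- 0.01
  b_bad <- b_tol
  b_bad$ventricle_mask <- binary_mask(array(1L, c(8, 8, 8)), affine = aff2)
  expect_false(validate_common_space(b_bad, tol = 1e-4)$pass)
})
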