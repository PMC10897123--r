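mk_mask <- function(idx, dims = c(6, 6, 6), vs = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[idx] <- 1L
  binary_mask(a, voxel_size = vs)
}

test_that("Dice matches hand counts, is symmetric, rejects empty pairs", {
  a <- mk_mask(1:4)
  b <- mk_mask(3:6)
  expect_equal(dice(a, b), 0.5)        # TP=2, FP=2, FN=2
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mk_mask(1:3), mk_mask(10:12)), 0)
  expect_error(dice(mk_mask(integer(0)), mk_mask(integer(0))), "empty")
  expect_error(dice(a, mk_mask(1:4, dims = c(7, 6, 6))), "share")
})

test_that("volumes convert voxel counts to mL via voxel dimensions", {
  expect_equal(volume_ml(mk_mask(1:3073, dims = c(20, 20, 20))), 3.073)
  expect_equal(volume_ml(mk_mask(integer(0))), 0)
  expect_equal(volume_ml(mk_mask(1:100, dims = c(10, 10, 10),
                                 vs = c(1, 1, 2))), 0.2)
  # additive over disjoint masks
  m1 <- mk_mask(1:10); m2 <- mk_mask(50:70)
  both <- mk_mask(c(1:10, 50:70))
  expect_equal(volume_ml(m1) + volume_ml(m2), volume_ml(both))
})

test_that("percentage volume differences are signed and folded correctly", {
  seg <- mk_mask(1:110, dims = c(10, 10, 10))
  ref <- mk_mask(1:100, dims = c(10, 10, 10))
  expect_equal(percent_volume_difference(seg, ref), 10)
  expect_equal(percent_volume_difference(ref, seg), -100 * 10 / 110)
  expect_equal(percent_volume_difference(ref, ref), 0)
  expect_equal(abs_percent_volume_difference(ref, seg), 100 * 10 / 110)
  expect_error(
    percent_volume_difference(seg, mk_mask(integer(0), dims = c(10, 10, 10))),
    "empty reference")
  # superset segmentation: dvol >= 0 and dice = 2|ref|/(|seg|+|ref|)
  expect_gte(percent_volume_difference(seg, ref), 0)
  expect_equal(dice(seg, ref), 2 * 100 / 210)
})

test_that("symmetric volume noise folds to the half-normal mean", {
  # per-subject signed error eps ~ N(0, 12 %): E|dvol| = 12*sqrt(2/pi)
  set.seed(55)
  dims <- c(12L, 12L, 12L)
  ref <- mk_mask(1:1000, dims = dims)
  absdv <- vapply(1:40, function(s) {
    eps <- rnorm(1, 0, 12)
    abs_percent_volume_difference(
      mk_mask(seq_len(round(1000 * (1 + eps / 100))), dims = dims), ref)
  }, numeric(1))
  target <- 12 * sqrt(2 / pi)
  sem <- stats::sd(absdv) / sqrt(length(absdv))
  expect_lt(abs(mean(absdv) - target), 3 * sem)
})

test_that("Pearson volume correlation has affine invariance and oracle", {
  v <- c(3.1, 2.2, 4.0, 3.6, 2.9)
  expect_equal(pearson_volume_correlation(v, 2 * v), 1)
  expect_equal(pearson_volume_correlation(v, -v + 10), -1)
  # frozen hand computation: cov/sd product for (1,2,3) vs (1,2,4)
  expect_equal(pearson_volume_correlation(c(1, 2, 3), c(1, 2, 4)),
               1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_error(pearson_volume_correlation(c(1, 1, 1), v[1:3]),
               "zero variance")
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  m5 <- matrix(c(10, 11, 12, 12, 8, 9, 15, 14, 11, 12),
               ncol = 2, byrow = TRUE)
  expect_equal(icc_absolute_volume(m5), 0.92, tolerance = 1e-12)
  expect_equal(icc_absolute_volume(m5), aov_icc21(m5), tolerance = 1e-9)
  set.seed(21)
  for (trial in 1:5) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n, 0, 3)
    expect_equal(icc_absolute_volume(m), aov_icc21(m), tolerance = 1e-9)
  }
})

test_that("ICC degenerate and identity cases behave", {
  expect_equal(icc_absolute_volume(cbind(c(10, 12, 8), c(10, 12, 8))), 1)
  expect_warning(r <- icc_absolute_volume(matrix(5, 3, 2)), "degenerate")
  expect_equal(r, 1)
  # consistency variant equals Pearson when columns share mean and variance
  set.seed(3)
  a <- rnorm(10); b <- rev(a)
  expect_equal(icc_absolute_volume(cbind(a, b), variant = "ICC3_1"),
               stats::cor(a, b), tolerance = 1e-9)
})
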