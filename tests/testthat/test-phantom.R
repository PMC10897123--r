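solid_ball <- function(radius, dims = c(32L, 32L, 32L)) {
  c0 <- (dims + 1) / 2
  idx <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
  a <- array(as.integer(sqrt((idx$i - c0[1])^2 + (idx$j - c0[2])^2 +
                             (idx$k - c0[3])^2) <= radius), dims)
  binary_mask(a)
}

test_that("perturb_mask identity, bias recovery and contract errors", {
  truth <- solid_ball(8, c(48L, 48L, 48L))
  container <- binary_mask(array(1L, c(48, 48, 48)))
  # no bias, no noise: the truth comes back exactly
  p0 <- perturb_mask(truth, container, 0, 0, seed = 1)
  expect_identical(p0$data, truth$data)
  expect_equal(dice(p0, truth), 1)
  # +30 % dilation with no noise: volume within 2 % of 1.3x truth
  p30 <- perturb_mask(truth, container, 30, 0, seed = 2)
  expect_lt(abs(voxel_count(p30) / (1.3 * voxel_count(truth)) - 1), 0.02)
  expect_true(all(p30$data >= truth$data))   # pure dilation keeps truth
  # -30 % erosion
  pm30 <- perturb_mask(truth, container, -30, 0, seed = 3)
  expect_lt(abs(voxel_count(pm30) / (0.7 * voxel_count(truth)) - 1), 0.02)
  expect_true(all(pm30$data <= truth$data))
  # impossible requests
  expect_error(perturb_mask(truth, container, -100, 0, seed = 4),
               "unreachable bias")
  tight <- binary_mask(truth$data)   # container == truth: nothing to add
  expect_error(perturb_mask(truth, tight, 30, 0, seed = 5),
               "unreachable bias")
  # result always inside the container
  pn <- perturb_mask(truth, container, 15, 0.3, seed = 6)
  expect_true(all(pn$data <= container$data))
})

test_that("perturb_mask is deterministic in its seed", {
  truth <- solid_ball(6)
  container <- binary_mask(array(1L, c(32, 32, 32)))
  a <- perturb_mask(truth, container, 20, 0.25, seed = 77)
  b <- perturb_mask(truth, container, 20, 0.25, seed = 77)
  c_ <- perturb_mask(truth, container, 20, 0.25, seed = 78)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c_$data))
})

test_that("boundary noise monotonically degrades expected Dice", {
  truth <- solid_ball(6)
  container <- binary_mask(array(1L, c(32, 32, 32)))
  d_low <- d_high <- numeric(50)
  for (s in 1:50) {
    d_low[s] <- dice(perturb_mask(truth, container, 0, 0.10, seed = s),
                     truth)
    d_high[s] <- dice(perturb_mask(truth, container, 0, 0.30, seed = s),
                      truth)
  }
  expect_gt(mean(d_low), mean(d_high))
  expect_true(all(d_low <= 1))
})

test_that("cohort generation is deterministic and honours the geometry", {
  co1 <- generate_cohort(small_spec(n_subjects = 2, seed = 5))
  co2 <- generate_cohort(small_spec(n_subjects = 2, seed = 5))
  for (i in 1:2) {
    b1 <- co1$subjects[[i]]; b2 <- co2$subjects[[i]]
    expect_identical(b1$truth_mask$data, b2$truth_mask$data)
    expect_identical(b1$intensities[[1]]$data, b2$intensities[[1]]$data)
    expect_identical(b1$chp_masks[["FLAIR"]]$r1$data,
                     b2$chp_masks[["FLAIR"]]$r1$data)
    # truth strictly inside the ventricles
    expect_true(all(b1$truth_mask$data <= b1$ventricle_mask$data))
    expect_lt(voxel_count(b1$truth_mask), voxel_count(b1$ventricle_mask))
  }
  # subject k does not depend on how many subjects are generated
  co3 <- generate_cohort(small_spec(n_subjects = 1, seed = 5))
  expect_identical(co3$subjects[[1]]$truth_mask$data,
                   co1$subjects[[1]]$truth_mask$data)
})

test_that("zero-perturbation cohorts hit every degenerate value", {
  sq <- default_sequence_params()
  sq$bias_pct <- 0
  sq$boundary_noise <- 0
  co <- generate_cohort(small_spec(n_subjects = 3, seed = 9, sequences = sq,
                                   rater_boundary_noise = 0))
  for (b in co$subjects) {
    for (s in names(b$chp_masks)) for (r in names(b$chp_masks[[s]])) {
      m <- b$chp_masks[[s]][[r]]
      expect_identical(m$data, b$truth_mask$data)
      expect_equal(dice(m, b$truth_mask), 1)
      expect_equal(percent_volume_difference(m, b$truth_mask), 0)
    }
  }
  fm <- frequency_map(lapply(co$subjects[1], function(b)
    b$chp_masks[["T1w"]]$r1))
  expect_equal(fm$data, co$subjects[[1]]$truth_mask$data + 0)
})

test_that("achieved volume bias recovers the target over a cohort", {
  co <- generate_cohort(small_spec(n_subjects = 20, seed = 17))
  sqp <- co$spec$sequences
  for (i in seq_len(nrow(sqp))) {
    dv <- vapply(co$subjects, function(b)
      percent_volume_difference(b$chp_masks[[sqp$sequence[i]]]$r1,
                                b$truth_mask), numeric(1))
    sem <- stats::sd(dv) / sqrt(length(dv))
    expect_lt(abs(mean(dv) - sqp$bias_pct[i]), 3 * sem)
  }
})

test_that("phantom SNR/CNR recover a specified intensity model", {
  sq <- data.frame(sequence = "SYN", chp_mean = 500, background_mean = 100,
                   noise_sd = 25, bias_pct = 0, boundary_noise = 0,
                   stringsAsFactors = FALSE)
  co <- generate_cohort(small_spec(n_subjects = 6, seed = 23, sequences = sq,
                                   raters = "r1"))
  est <- t(vapply(co$subjects, function(b) {
    bg <- build_background_roi(b$ventricle_mask,
                               list(b$chp_masks[["SYN"]]$r1))
    c(snr(b$intensities[["SYN"]], b$truth_mask, bg),
      cnr(b$intensities[["SYN"]], b$truth_mask, bg))
  }, numeric(2)))
  for (j in 1:2) {
    target <- c(500 / 25, (500 - 100) / 25)[j]
    sem <- stats::sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, j]) - target), 3 * sem)
  }
})

test_that("cohort trees round-trip through disk", {
  co <- generate_cohort(small_spec(n_subjects = 2, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  back <- read_cohort(dir, sequences = co$spec$sequences$sequence,
                      raters = co$spec$raters)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$ventricle_mask$data,
                     co$subjects[[i]]$ventricle_mask$data)
    expect_identical(back[[i]]$chp_masks[["T1w"]]$r2$data,
                     co$subjects[[i]]$chp_masks[["T1w"]]$r2$data)
    expect_lt(max(abs(back[[i]]$intensities[["FLAIR"]]$data -
                      co$subjects[[i]]$intensities[["FLAIR"]]$data)), 1e-6)
  }
})
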