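# Independent brute-force oracles: every metric is re-derived here by
# direct voxel enumeration / textbook formulas, sharing no code with the
# package implementations they check.

rand_mask <- function(dims = c(16L, 16L, 16L), p = 0.4,
                      voxel_size = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims),
              voxel_size = voxel_size)
}

rand_volume <- function(dims = c(16L, 16L, 16L), voxel_size = c(1, 1, 1)) {
  volume_image(array(stats::rnorm(prod(dims), 100, 20), dims),
               voxel_size = voxel_size)
}

ball_offsets_oracle <- function(radius, vs) {
  r <- floor(radius / vs)
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  nrm <- sqrt((g[, 1] * vs[1])^2 + (g[, 2] * vs[2])^2 + (g[, 3] * vs[3])^2)
  g[nrm <= radius + 1e-9, , drop = FALSE]
}

# per-voxel neighborhood check, outside-grid counts as background
brute_erode <- function(mask, radius) {
  vs <- voxel_size(mask)
  off <- ball_offsets_oracle(radius, vs)
  a <- mask$data
  d <- dim(a)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (a[i, j, k] == 0L) next
    keep <- TRUE
    for (r in seq_len(nrow(off))) {
      ii <- i + off[r, 1]; jj <- j + off[r, 2]; kk <- k + off[r, 3]
      if (ii < 1L || jj < 1L || kk < 1L ||
          ii > d[1] || jj > d[2] || kk > d[3] || a[ii, jj, kk] == 0L) {
        keep <- FALSE
        break
      }
    }
    if (keep) out[i, j, k] <- 1L
  }
  binary_mask(out, affine = mask$affine)
}

brute_dice <- function(seg, ref) {
  tp <- 0L; fp <- 0L; fn <- 0L
  s <- seg$data; r <- ref$data
  for (i in seq_along(s)) {
    if (s[i] == 1L && r[i] == 1L) tp <- tp + 1L
    else if (s[i] == 1L) fp <- fp + 1L
    else if (r[i] == 1L) fn <- fn + 1L
  }
  2 * tp / (2 * tp + fp + fn)
}

brute_snr <- function(img, roi, bg) {
  rv <- img$data[roi$data == 1L]
  bv <- img$data[bg$data == 1L]
  nb <- length(bv)
  sdb <- sqrt(sum((bv - sum(bv) / nb)^2) / (nb - 1))
  (sum(rv) / length(rv)) / sdb
}

brute_cnr <- function(img, roi, bg) {
  rv <- img$data[roi$data == 1L]
  bv <- img$data[bg$data == 1L]
  nb <- length(bv)
  sdb <- sqrt(sum((bv - sum(bv) / nb)^2) / (nb - 1))
  (sum(rv) / length(rv) - sum(bv) / nb) / sdb
}

brute_dvol_pct <- function(seg, ref) {
  vs <- voxel_size(seg)
  v_s <- sum(seg$data) * prod(vs)
  v_r <- sum(ref$data) * prod(vs)
  100 * (v_s - v_r) / v_r
}

# per-subject slice errors along one voxel axis, by explicit slicing
brute_slice_errors <- function(seg, ref, axis_vox) {
  d <- dim(ref$data)
  tot <- sum(ref$data)
  vapply(seq_len(d[axis_vox]), function(i) {
    sl <- switch(axis_vox,
                 list(seg$data[i, , ], ref$data[i, , ]),
                 list(seg$data[, i, ], ref$data[, i, ]),
                 list(seg$data[, , i], ref$data[, , i]))
    100 * (sum(sl[[1]]) - sum(sl[[2]])) / tot
  }, numeric(1))
}

brute_freq <- function(masks) {
  acc <- array(0, dim(masks[[1]]$data))
  for (m in masks) acc <- acc + m$data
  acc / length(masks)
}

# ICC(2,1) via stats::aov two-way mean squares (independent route)
aov_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, data = df))[["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# compact phantom used where full-size cohorts are unnecessary
small_spec <- function(n_subjects = 4, seed = 1L, ...) {
  phantom_spec(n_subjects = n_subjects,
               grid_shape = c(48L, 48L, 48L),
               vent_center_offset_mm = c(11, 0, 0),
               vent_radii_mm = c(5, 12, 6),
               chp_half_length_mm = 9,
               chp_radius_mm = 1.8,
               chp_bow_mm = 1.5,
               chp_arch_mm = 2,
               seed = seed, ...)
}
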