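# Synthetic phantom cohorts with known ground truth.
#
# Each subject carries two ellipsoidal lateral-ventricle compartments, each
# containing a thin curved tube of "choroid plexus" running along y. Per
# sequence, the intensity volume is background_mean inside the ventricles,
# chp_mean inside the truth ChP, 0 elsewhere, plus stationary i.i.d.
# Gaussian noise (the pipeline's SNR/CNR definitions involve only first and
# second moments, so Rician realism is not needed). Segmentation masks are
# perturbations of the truth with a controlled signed volume bias
# (distance-ordered dilation/erosion, exact in expectation) and controlled
# boundary noise (volume-preserving random flips), emulating a systematic
# FLAIR-like overestimation and rater disagreement.

#' Default per-sequence phantom parameters
#'
#' Intensity means are parameterized so that, with the truth ChP as ROI and
#' pure-noise background SD, the implied SNR (= chp_mean/noise_sd) and CNR
#' (= (chp_mean - background_mean)/noise_sd) match the contrast levels
#' typical of each sequence (T1w 13.73/7.44, FLAIR 13.09/10.77, CE-T1w
#' 23.77/18.49). Volume biases emulate FLAIR's systematic overestimation
#' (+28.02%) and T1w's small bias (+3.52%) against a contrast-enhanced
#' reference; boundary noise levels set the Dice degradation.
#'
#' @return data.frame with one row per sequence: chp_mean, background_mean,
#'   noise_sd, bias_pct, boundary_noise.
#' @export
default_sequence_params <- function() {
  data.frame(
    sequence = c("T1w", "FLAIR", "CE-T1w"),
    chp_mean = c(343.25, 327.25, 594.25),
    background_mean = c(157.25, 58.0, 132.0),
    noise_sd = c(25, 25, 25),
    bias_pct = c(3.52, 28.02, 0),
    boundary_noise = c(0.46, 0.37, 0.05),
    stringsAsFactors = FALSE)
}

#' Phantom cohort specification
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param grid_shape Grid dimensions (default 96^3).
#' @param voxel_size Voxel dimensions in mm (default 1 mm isotropic).
#' @param vent_center_offset_mm Ventricle center offset from the grid
#'   center, mirrored left/right in x.
#' @param vent_radii_mm Ellipsoid semi-axes (x, y, z) in mm.
#' @param vent_center_jitter_sd_mm Per-subject SD of ventricle center
#'   jitter, mm.
#' @param vent_radius_jitter_frac Per-subject fractional SD of the
#'   semi-axes.
#' @param chp_half_length_mm Half-extent of the ChP curve along y, mm.
#' @param chp_radius_mm Tube radius of the ChP structure, mm.
#' @param chp_bow_mm Lateral bowing amplitude of the curve, mm.
#' @param chp_arch_mm Vertical arching amplitude of the curve, mm.
#' @param chp_jitter_sd_mm Per-subject SD on the curve shape parameters, mm.
#' @param sequences data.frame as from [default_sequence_params()].
#' @param raters Rater ids; the first is the primary rater whose masks are
#'   the per-sequence segmentations.
#' @param rater_boundary_noise Boundary-flip probability for non-primary
#'   raters (a re-draw around the primary mask; bias 0).
#' @param seed Integer master seed; all randomness flows from it.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(n_subjects = 30,
                         grid_shape = c(96L, 96L, 96L),
                         voxel_size = c(1, 1, 1),
                         vent_center_offset_mm = c(15, 0, 0),
                         vent_radii_mm = c(7, 20, 9),
                         vent_center_jitter_sd_mm = 1,
                         vent_radius_jitter_frac = 0.05,
                         chp_half_length_mm = 16,
                         chp_radius_mm = 2.2,
                         chp_bow_mm = 2,
                         chp_arch_mm = 3,
                         chp_jitter_sd_mm = 0.5,
                         sequences = default_sequence_params(),
                         raters = c("r1", "r2"),
                         rater_boundary_noise = 0.15,
                         seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               grid_shape = as.integer(grid_shape),
               voxel_size = as.numeric(voxel_size),
               vent_center_offset_mm = vent_center_offset_mm,
               vent_radii_mm = vent_radii_mm,
               vent_center_jitter_sd_mm = vent_center_jitter_sd_mm,
               vent_radius_jitter_frac = vent_radius_jitter_frac,
               chp_half_length_mm = chp_half_length_mm,
               chp_radius_mm = chp_radius_mm,
               chp_bow_mm = chp_bow_mm,
               chp_arch_mm = chp_arch_mm,
               chp_jitter_sd_mm = chp_jitter_sd_mm,
               sequences = sequences,
               raters = as.character(raters),
               rater_boundary_noise = rater_boundary_noise,
               seed = as.integer(seed))
  stopifnot(spec$n_subjects >= 1L,
            length(spec$grid_shape) == 3L, all(spec$grid_shape >= 8L),
            all(spec$voxel_size > 0),
            all(spec$vent_radii_mm > 0), spec$chp_radius_mm > 0,
            spec$chp_half_length_mm > 0,
            all(spec$sequences$noise_sd > 0),
            length(spec$raters) >= 1L)
  class(spec) <- "phantom_spec"
  spec
}

# ---- mask perturbation ----------------------------------------------------

# Distance shells: voxels of `cand` at exact Euclidean (mm) distance d from
# `seed_region`, enumerated in ascending d. Selects whole shells until
# `need` would be exceeded, then samples the marginal shell independently
# with probability need/|shell| — so the expected selected count equals
# `need` exactly and the geometry stays a physical-distance dilation.
select_by_distance <- function(seed_region, cand, need, vs) {
  sel <- array(FALSE, dim(seed_region))
  covered <- seed_region
  processed_norm <- 0
  radius <- 2 * max(vs)
  max_radius <- sum(dim(seed_region) * vs)   # grid diagonal bound
  while (need > 1e-9) {
    se <- structuring_element(radius, vs)
    norms <- attr(se, "norms")
    off <- unclass(se)
    ord <- order(norms)
    off <- off[ord, , drop = FALSE]
    norms <- norms[ord]
    for (d in unique(norms)) {
      if (d <= processed_norm) next
      newcov <- array(FALSE, dim(seed_region))
      for (r in which(norms == d))
        newcov <- newcov | shift_logical(seed_region, off[r, ])
      layer <- newcov & cand & !covered
      covered <- covered | newcov
      nl <- sum(layer)
      if (nl > 0L) {
        if (need >= nl) {
          sel <- sel | layer
          need <- need - nl
        } else {
          idx <- which(layer)
          sel[idx[stats::runif(nl) < need / nl]] <- TRUE
          need <- 0
        }
      }
      processed_norm <- d
      if (need <= 1e-9) break
    }
    if (need > 1e-9) {
      if (sum(cand & !covered) == 0L)
        stop("unreachable bias: container too tight to supply ",
             ceiling(need), " more voxels")
      radius <- radius * 2
      if (radius > max_radius)
        stop("unreachable bias: no candidates within the grid")
    }
  }
  sel
}

# Volume-preserving boundary noise: each inner-boundary (face-connected)
# mask voxel is flipped off with probability p; outer-shell voxels inside
# the container are flipped on with probability p * n_inner / n_outer, so
# the expected volume change is zero while Dice against the unperturbed
# mask degrades monotonically in p.
flip_boundary <- function(mask, container, p) {
  d <- dim(mask)
  face <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  all_nb <- array(TRUE, d)
  any_nb <- array(FALSE, d)
  for (r in 1:6) {
    s <- shift_logical(mask, face[r, ])
    all_nb <- all_nb & s
    any_nb <- any_nb | s
  }
  inner <- mask & !all_nb
  outer <- !mask & container & any_nb
  ni <- sum(inner)
  no <- sum(outer)
  if (ni > 0L) {
    idx <- which(inner)
    mask[idx[stats::runif(ni) < p]] <- FALSE
  }
  if (no > 0L && ni > 0L) {
    q <- min(1, p * ni / no)
    idx <- which(outer)
    mask[idx[stats::runif(no) < q]] <- TRUE
  }
  mask
}

#' Perturb a ground-truth mask with controlled volume bias and boundary noise
#'
#' The bias step grows (or shrinks) the truth through exact Euclidean
#' distance shells — a physical-distance dilation/erosion in mm, mirroring
#' boundary effects like FLAIR's intrinsic blurring — with the marginal
#' shell sampled so the expected signed volume difference equals
#' `target_bias_percent` exactly. The noise step then flips boundary voxels
#' at rate `boundary_noise`, preserving expected volume while degrading
#' Dice. Deterministic given `seed`; the result is always a subset of
#' `container`.
#'
#' @param truth [binary_mask] of the true structure (subset of `container`).
#' @param container [binary_mask] the result must stay inside (the
#'   ventricles).
#' @param target_bias_percent Signed target volume difference vs. truth, %.
#'   Must be > -100 (the structure cannot vanish entirely).
#' @param boundary_noise Flip probability in [0, 1].
#' @param seed Integer seed.
#' @return Perturbed [binary_mask].
#' @export
perturb_mask <- function(truth, container, target_bias_percent = 0,
                         boundary_noise = 0, seed = 1L) {
  stopifnot(inherits(truth, "binary_mask"), inherits(container, "binary_mask"),
            boundary_noise >= 0, boundary_noise <= 1)
  assert_same_geometry(truth, container)
  t_arr <- truth$data == 1L
  c_arr <- container$data == 1L
  if (any(t_arr & !c_arr)) stop("truth must be a subset of the container")
  n0 <- sum(t_arr)
  if (n0 == 0L) stop("empty truth mask")
  n_target <- n0 * (1 + target_bias_percent / 100)
  if (n_target < 1)
    stop("unreachable bias: cannot remove the entire structure ",
         "(target_bias_percent <= -100)")
  vs <- voxel_size(truth)
  out <- with_seed(seed, {
    mask <- t_arr
    if (target_bias_percent > 0) {
      add <- select_by_distance(t_arr, c_arr & !t_arr, n_target - n0, vs)
      mask <- mask | add
    } else if (target_bias_percent < 0) {
      drop <- select_by_distance(!t_arr, t_arr, n0 - n_target, vs)
      mask <- mask & !drop
    }
    if (boundary_noise > 0) mask <- flip_boundary(mask, c_arr, boundary_noise)
    mask
  })
  binary_mask(out, affine = truth$affine)
}

# ---- geometry -------------------------------------------------------------

ellipsoid_arr <- function(xs, ys, zs, center, radii) {
  a <- ((xs - center[1]) / radii[1])^2
  b <- ((ys - center[2]) / radii[2])^2
  cc <- ((zs - center[3]) / radii[3])^2
  outer(outer(a, b, "+"), cc, "+") <= 1
}

# Tube of radius rad (mm) around a polyline of world-mm points.
tube_arr <- function(xs, ys, zs, pts, rad) {
  d <- c(length(xs), length(ys), length(zs))
  out <- array(FALSE, d)
  r2 <- rad^2
  for (p in seq_len(nrow(pts))) {
    ix <- which(abs(xs - pts[p, 1]) <= rad)
    iy <- which(abs(ys - pts[p, 2]) <= rad)
    iz <- which(abs(zs - pts[p, 3]) <= rad)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - pts[p, 1])^2
    dy2 <- (ys[iy] - pts[p, 2])^2
    dz2 <- (zs[iz] - pts[p, 3])^2
    loc <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    out[ix, iy, iz] <- out[ix, iy, iz] | loc
  }
  out
}

generate_geometry <- function(spec, subject) {
  d <- spec$grid_shape
  vs <- spec$voxel_size
  center0 <- (d - 1) / 2
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- -center0 * vs            # world origin at the grid center
  xs <- ((0:(d[1] - 1)) - center0[1]) * vs[1]
  ys <- ((0:(d[2] - 1)) - center0[2]) * vs[2]
  zs <- ((0:(d[3] - 1)) - center0[3]) * vs[3]
  vent <- array(FALSE, d)
  chp <- array(FALSE, d)
  with_seed(sub_seed(spec$seed, subject, 1L), {
    for (side in c(-1, 1)) {
      cen <- spec$vent_center_offset_mm * c(side, 1, 1) +
        stats::rnorm(3, 0, spec$vent_center_jitter_sd_mm)
      rad <- spec$vent_radii_mm *
        pmax(0.5, 1 + stats::rnorm(3, 0, spec$vent_radius_jitter_frac))
      v_side <- ellipsoid_arr(xs, ys, zs, cen, rad)
      half <- spec$chp_half_length_mm +
        stats::rnorm(1, 0, spec$chp_jitter_sd_mm)
      bow <- spec$chp_bow_mm + stats::rnorm(1, 0, spec$chp_jitter_sd_mm)
      arch <- spec$chp_arch_mm + stats::rnorm(1, 0, spec$chp_jitter_sd_mm)
      tseq <- seq(-1, 1, length.out = max(41L, ceiling(4 * half)))
      pts <- cbind(cen[1] + side * bow * (1 - tseq^2),
                   cen[2] + tseq * half,
                   cen[3] + arch * (0.5 - tseq^2))
      c_side <- tube_arr(xs, ys, zs, pts, spec$chp_radius_mm) & v_side
      if (sum(c_side) == 0L)
        stop("ChP region empty at requested geometry: grid too coarse")
      vent <- vent | v_side
      chp <- chp | c_side
    }
  })
  list(ventricles = binary_mask(vent, affine = aff),
       truth = binary_mask(chp, affine = aff),
       affine = aff)
}

# ---- cohort ---------------------------------------------------------------

generate_subject <- function(spec, subject) {
  geo <- generate_geometry(spec, subject)
  d <- spec$grid_shape
  seqs <- spec$sequences
  intensities <- list()
  chp_masks <- list()
  for (i in seq_len(nrow(seqs))) {
    sq <- seqs$sequence[i]
    base <- array(0, d)
    base[geo$ventricles$data == 1L] <- seqs$background_mean[i]
    base[geo$truth$data == 1L] <- seqs$chp_mean[i]
    img <- with_seed(sub_seed(spec$seed, subject, 100L + i), {
      base + array(stats::rnorm(prod(d), 0, seqs$noise_sd[i]), d)
    })
    intensities[[sq]] <- volume_image(img, affine = geo$affine)
    masks <- list()
    masks[[spec$raters[1]]] <- perturb_mask(
      geo$truth, geo$ventricles,
      target_bias_percent = seqs$bias_pct[i],
      boundary_noise = seqs$boundary_noise[i],
      seed = sub_seed(spec$seed, subject, 200L + i))
    for (r in seq_along(spec$raters)[-1]) {
      masks[[spec$raters[r]]] <- perturb_mask(
        masks[[spec$raters[1]]], geo$ventricles,
        target_bias_percent = 0,
        boundary_noise = spec$rater_boundary_noise,
        seed = sub_seed(spec$seed, subject, 300L + i * 10L + r))
    }
    chp_masks[[sq]] <- masks
  }
  subject_bundle(sprintf("sub-%03d", subject), intensities, chp_masks,
                 geo$ventricles, truth_mask = geo$truth)
}

#' Generate a phantom cohort
#'
#' Deterministic given `spec$seed`: per-subject substreams are derived by
#' fixed offsets, so subject k is identical no matter how many subjects are
#' generated.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_cohort`: list with `subjects` (list of
#'   [subject_bundle]s, each carrying its `truth_mask`), `spec`, and
#'   `params` (data.frame of ground-truth generator parameters per subject
#'   and sequence, for recovery tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  subjects <- lapply(seq_len(spec$n_subjects),
                     function(i) generate_subject(spec, i))
  params <- do.call(rbind, lapply(subjects, function(b) {
    data.frame(subject_id = b$subject_id,
               sequence = spec$sequences$sequence,
               target_bias_pct = spec$sequences$bias_pct,
               boundary_noise = spec$sequences$boundary_noise,
               chp_mean = spec$sequences$chp_mean,
               background_mean = spec$sequences$background_mean,
               noise_sd = spec$sequences$noise_sd,
               truth_vol_ml = volume_ml(b$truth_mask),
               stringsAsFactors = FALSE)
  }))
  structure(list(subjects = subjects, spec = spec, params = params),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subject(s), grid %s, seed %d\n",
              length(x$subjects),
              paste(x$spec$grid_shape, collapse = "x"), x$spec$seed))
  invisible(x)
}

#' Write a phantom cohort as a NIfTI directory tree
#'
#' One directory per subject holding `<sequence>.nii.gz`,
#' `<sequence>_chp_<rater>.nii.gz`, `ventricles.nii.gz` and
#' `chp_truth.nii.gz`, plus a cohort-level `ground_truth.tsv` parameter
#' record for recovery tests.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in cohort$subjects) {
    sd_ <- file.path(dir, b$subject_id)
    dir.create(sd_, showWarnings = FALSE)
    for (sq in names(b$intensities)) {
      write_volume(b$intensities[[sq]], file.path(sd_, paste0(sq, ".nii.gz")))
      for (r in names(b$chp_masks[[sq]]))
        write_volume(b$chp_masks[[sq]][[r]],
                     file.path(sd_, paste0(sq, "_chp_", r, ".nii.gz")))
    }
    write_volume(b$ventricle_mask, file.path(sd_, "ventricles.nii.gz"))
    if (!is.null(b$truth_mask))
      write_volume(b$truth_mask, file.path(sd_, "chp_truth.nii.gz"))
  }
  utils::write.table(cohort$params, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
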