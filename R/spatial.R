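# Spatial variability on a common template grid: slice-wise signed volume
# error profiles along anatomical axes, and voxel-wise frequency maps.
#
# Axis convention: anatomical labels ("x", "y", "z") are mapped to voxel
# axes by `axis_map` (default identity, correct for axis-aligned template
# grids such as resampled MNI152). Slice coordinates are reported as world
# mm of slice centers, so template-space locations like "z = -12 mm" are
# addressable. Oblique affines are not supported here.

axis_index <- function(axis, axis_map = c(x = 1L, y = 2L, z = 3L)) {
  if (!axis %in% names(axis_map))
    stop("unknown axis '", axis, "'; expected one of ",
         paste(names(axis_map), collapse = ", "))
  as.integer(axis_map[[axis]])
}

slice_world_mm <- function(template, axis_vox) {
  d <- dim(template$data)
  center0 <- (d - 1) / 2            # 0-based voxel center of the grid
  vapply(seq_len(d[axis_vox]), function(i) {
    idx <- center0
    idx[axis_vox] <- i - 1
    (template$affine %*% c(idx, 1))[axis_vox]
  }, numeric(1))
}

slice_counts <- function(mask, axis_vox) {
  apply(mask$data, axis_vox, sum)
}

#' Slice-wise volume error profile along a template axis
#'
#' For each subject s and slice i along the chosen anatomical axis the
#' signed error is err_s(i) = 100 * (count_seg(i) - count_ref(i)) /
#' count_ref_total, i.e. per-slice voxel surplus normalized by the subject's
#' whole reference volume (division-safe even on slices where the reference
#' is empty). The profile reports the mean and SD of err_s(i) over subjects.
#' Summing a subject's slice errors over i recovers that subject's signed
#' percentage volume difference exactly.
#'
#' @param seg_masks,ref_masks Equal-length lists of [binary_mask]s on one
#'   template grid, one pair per subject.
#' @param axis Anatomical axis label: "z" (axial-wise) or "y" (coronal-wise);
#'   "x" also accepted.
#' @param axis_map Named integer vector mapping anatomical labels to voxel
#'   axes.
#' @return data.frame with class `slice_error_profile`: axis, slice_index,
#'   slice_mm, mean_error_pct, sd_error_pct, n_subjects.
#' @export
slice_error_profile <- function(seg_masks, ref_masks, axis = "z",
                                axis_map = c(x = 1L, y = 2L, z = 3L)) {
  stopifnot(length(seg_masks) == length(ref_masks), length(seg_masks) >= 1L)
  av <- axis_index(axis, axis_map)
  ref1 <- ref_masks[[1L]]
  err <- vapply(seq_along(seg_masks), function(s) {
    seg <- seg_masks[[s]]
    ref <- ref_masks[[s]]
    assert_same_geometry(seg, ref1, "masks and template grid")
    assert_same_geometry(seg, ref, "seg and ref masks")
    tot <- voxel_count(ref)
    if (tot == 0L) stop("empty reference mask for subject ", s)
    100 * (slice_counts(seg, av) - slice_counts(ref, av)) / tot
  }, numeric(dim(ref1$data)[av]))
  err <- matrix(err, ncol = length(seg_masks))   # slices x subjects
  out <- data.frame(
    axis = axis,
    slice_index = seq_len(nrow(err)),
    slice_mm = slice_world_mm(ref1, av),
    mean_error_pct = rowMeans(err),
    sd_error_pct = if (ncol(err) > 1L) apply(err, 1, stats::sd) else NA_real_,
    n_subjects = ncol(err),
    stringsAsFactors = FALSE)
  class(out) <- c("slice_error_profile", "data.frame")
  attr(out, "per_subject") <- err
  out
}

#' Voxel-wise frequency (probability) map over a cohort
#'
#' Each voxel's value is the fraction of subjects whose mask covers it — an
#' empirical probability atlas. No thresholding or smoothing is applied.
#'
#' @param masks Non-empty list of [binary_mask]s on one shared grid.
#' @param label Optional sequence label stored on the result.
#' @return A [volume_image] with values k/n; attributes `n_subjects`,
#'   `label`.
#' @export
frequency_map <- function(masks, label = NULL) {
  stopifnot(length(masks) >= 1L)
  ref <- masks[[1L]]
  acc <- array(0, dim(ref$data))
  for (m in masks) {
    assert_same_geometry(m, ref)
    acc <- acc + m$data
  }
  out <- volume_image(acc / length(masks), affine = ref$affine)
  attr(out, "n_subjects") <- length(masks)
  attr(out, "label") <- label
  class(out) <- c("frequency_map", class(out))
  out
}

#' Difference of two frequency maps
#'
#' freq(sequence) - freq(reference), voxel-wise; positive where the sequence
#' labels ChP more often than the reference does.
#'
#' @param seq_map,ref_map [frequency_map()]s built over the same cohort
#'   (same `n_subjects`) and grid.
#' @return A [volume_image] with values in [-1, 1].
#' @export
frequency_difference_map <- function(seq_map, ref_map) {
  stopifnot(inherits(seq_map, "frequency_map"),
            inherits(ref_map, "frequency_map"))
  if (!identical(attr(seq_map, "n_subjects"), attr(ref_map, "n_subjects")))
    stop("frequency maps come from cohorts of different size")
  assert_same_geometry(seq_map, ref_map, "frequency maps")
  out <- volume_image(seq_map$data - ref_map$data, affine = seq_map$affine)
  attr(out, "pair") <- c(attr(seq_map, "label"), attr(ref_map, "label"))
  out
}
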