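# Overlap and volume agreement metrics between a segmentation and a
# reference mask, plus cohort-level Pearson correlation and inter-rater ICC.

#' Dice similarity coefficient
#'
#' 2*TP / (2*TP + FP + FN) with TP = |seg & ref|, FP = |seg \ ref|,
#' FN = |ref \ seg|. Symmetric in its arguments. Two empty masks are an
#' error, not 0 or 1: that situation signals broken upstream masks, never a
#' real measurement.
#'
#' @param seg,ref [binary_mask]s on the same grid.
#' @return Scalar in [0, 1].
#' @export
dice <- function(seg, ref) {
  assert_same_geometry(seg, ref)
  tp <- sum(seg$data == 1L & ref$data == 1L)
  ns <- voxel_count(seg)
  nr <- voxel_count(ref)
  if (ns == 0L && nr == 0L)
    stop("Dice undefined: both masks are empty")
  2 * tp / (ns + nr)
}

#' Mask volume in millilitres
#'
#' voxel_count * dx*dy*dz / 1000 (mm^3 to mL), using the voxel dimensions
#' derived from the mask's affine.
#'
#' @param mask A [binary_mask].
#' @return Volume in mL.
#' @export
volume_ml <- function(mask) {
  voxel_count(mask) * prod(voxel_size(mask)) / 1000
}

#' Signed percentage volume difference
#'
#' 100 * (Vol_seg - Vol_ref) / Vol_ref; positive means the segmentation
#' overestimates the reference.
#'
#' @inheritParams dice
#' @return Signed percentage.
#' @export
percent_volume_difference <- function(seg, ref) {
  assert_same_geometry(seg, ref)
  vr <- volume_ml(ref)
  if (vr == 0) stop("empty reference mask")
  100 * (volume_ml(seg) - vr) / vr
}

#' Absolute percentage volume difference
#'
#' @inheritParams dice
#' @return |[percent_volume_difference()]|.
#' @export
abs_percent_volume_difference <- function(seg, ref) {
  abs(percent_volume_difference(seg, ref))
}

#' Pearson correlation between two per-subject volume series
#'
#' One point per subject (volumes in mL); used cohort-wise to compare the
#' volumes a sequence yields against the reference sequence.
#'
#' @param vols_a,vols_b Equal-length numeric vectors, length >= 3.
#' @return Product-moment correlation in [-1, 1].
#' @export
pearson_volume_correlation <- function(vols_a, vols_b) {
  stopifnot(length(vols_a) == length(vols_b), length(vols_a) >= 3L)
  if (stats::sd(vols_a) == 0 || stats::sd(vols_b) == 0)
    stop("zero variance in a volume series")
  stats::cor(vols_a, vols_b, method = "pearson")
}

#' Overlap/volume metrics for one segmentation-reference pair
#'
#' @inheritParams dice
#' @param subject_id,seg_label,ref_label Identifier strings for the output
#'   row.
#' @return One-row data.frame: dsc, vol_seg_ml, vol_ref_ml, dvol_pct,
#'   abs_dvol_pct.
#' @export
overlap_row <- function(seg, ref, subject_id = NA_character_,
                        seg_label = "seg", ref_label = "ref") {
  dv <- percent_volume_difference(seg, ref)
  data.frame(subject_id = subject_id, seg_label = seg_label,
             ref_label = ref_label, dsc = dice(seg, ref),
             vol_seg_ml = volume_ml(seg), vol_ref_ml = volume_ml(ref),
             dvol_pct = dv, abs_dvol_pct = abs(dv),
             stringsAsFactors = FALSE)
}

#' Inter-rater ICC on absolute volumes
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (Shrout-Fleiss ICC(2,1)), computed from the two-way ANOVA mean squares of
#' the subjects x raters volume matrix:
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)),
#' where MS_R are subject (row) mean squares, MS_C rater (column) mean
#' squares and MS_E residual mean squares. The consistency variant ICC(3,1)
#' = (MS_R - MS_E) / (MS_R + (k-1) MS_E) is also available.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, >= 2 rows and >= 2 columns.
#' @param variant "ICC2_1" (absolute agreement, default) or "ICC3_1"
#'   (consistency).
#' @return Scalar ICC. A matrix whose cells are all identical is degenerate
#'   (no variance to apportion) and returns 1 with a warning.
#' @export
icc_absolute_volume <- function(ratings, variant = c("ICC2_1", "ICC3_1")) {
  variant <- match.arg(variant)
  ratings <- as.matrix(ratings)
  stopifnot(is.numeric(ratings), !anyNA(ratings),
            nrow(ratings) >= 2L, ncol(ratings) >= 2L)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (max(ratings) == min(ratings)) {
    warning("all ratings identical: ICC degenerate, returning 1")
    return(1)
  }
  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_r <- k * sum((row_m - gm)^2)
  ss_c <- n * sum((col_m - gm)^2)
  ss_tot <- sum((ratings - gm)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (variant == "ICC2_1")
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  else
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}
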