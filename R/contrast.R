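# Contrast metrics between the ChP ROI and the ventricular background ROI.
# Both are ratios normalized by the SD of the background intensities:
#   SNR = mean(ROI) / sd(background)
#   CNR = (mean(ROI) - mean(background)) / sd(background)
# sd() is the sample SD (n-1 denominator): the background is a sample of the
# noise process. Intensities are used raw; both metrics are invariant under
# global positive scaling of the image.

roi_values <- function(intensity, mask) {
  assert_same_geometry(intensity, mask, "intensity and mask")
  intensity$data[mask$data == 1L]
}

check_contrast_inputs <- function(intensity, roi, background) {
  rv <- roi_values(intensity, roi)
  bv <- roi_values(intensity, background)
  if (length(rv) < 1L) stop("empty ROI")
  if (length(bv) < 2L) stop("background needs >= 2 voxels")
  s <- stats::sd(bv)
  if (!is.finite(s) || s == 0)
    stop("zero background SD: constant background region")
  list(rv = rv, bv = bv, sd = s)
}

#' Signal-to-noise ratio of an ROI against a background region
#'
#' @param intensity [volume_image] of raw intensities.
#' @param roi [binary_mask] of the signal region (the ChP segmentation).
#' @param background [binary_mask] from [build_background_roi()].
#' @return Scalar SNR = mean(ROI values) / sd(background values).
#' @export
snr <- function(intensity, roi, background) {
  x <- check_contrast_inputs(intensity, roi, background)
  mean(x$rv) / x$sd
}

#' Contrast-to-noise ratio of an ROI against a background region
#'
#' @inheritParams snr
#' @return Scalar CNR = (mean(ROI) - mean(background)) / sd(background);
#'   negative when the ROI is darker than the background.
#' @export
cnr <- function(intensity, roi, background) {
  x <- check_contrast_inputs(intensity, roi, background)
  (mean(x$rv) - mean(x$bv)) / x$sd
}

#' Per-subject, per-sequence contrast table
#'
#' Builds the background ROI once per subject (ventricles minus the union of
#' every sequence's ChP mask, eroded), then computes SNR and CNR for each
#' sequence with that sequence's own ChP mask as ROI.
#'
#' @param bundle A [subject_bundle].
#' @param rater Rater id whose masks define the ROIs (default first rater).
#' @param erosion_radius_mm Background erosion radius, mm.
#' @return data.frame: subject_id, sequence, snr, cnr, roi_n, background_n.
#' @export
contrast_table <- function(bundle, rater = NULL, erosion_radius_mm = 2) {
  seqs <- names(bundle$intensities)
  if (is.null(rater)) rater <- names(bundle$chp_masks[[seqs[1]]])[1]
  masks <- lapply(seqs, function(s) bundle$chp_masks[[s]][[rater]])
  bg <- build_background_roi(bundle$ventricle_mask, masks, erosion_radius_mm)
  rows <- lapply(seq_along(seqs), function(i) {
    data.frame(subject_id = bundle$subject_id, sequence = seqs[i],
               snr = snr(bundle$intensities[[i]], masks[[i]], bg),
               cnr = cnr(bundle$intensities[[i]], masks[[i]], bg),
               roi_n = voxel_count(masks[[i]]),
               background_n = voxel_count(bg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
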