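# 3D binary morphology with structuring elements defined in physical mm.
# The spherical kernel is a closed ball: an integer voxel offset belongs to
# the element iff its world-mm Euclidean norm is <= radius_mm, so the kernel
# adapts to anisotropic voxels (e.g. radius 2 mm on (1,1,2) mm voxels spans
# +/-2 voxels in-plane but only +/-1 through-plane).

#' Spherical structuring element in physical units
#'
#' @param radius_mm Ball radius in mm (>= 0).
#' @param voxel_size Length-3 voxel dimensions in mm.
#' @return A `structuring_element`: matrix of integer voxel offsets (rows),
#'   each with mm-norm <= `radius_mm`; always contains the zero offset and is
#'   symmetric under negation.
#' @export
structuring_element <- function(radius_mm, voxel_size) {
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0),
            is.finite(radius_mm), radius_mm >= 0)
  reach <- floor(radius_mm / voxel_size)
  g <- expand.grid(i = -reach[1]:reach[1],
                   j = -reach[2]:reach[2],
                   k = -reach[3]:reach[3])
  off <- as.matrix(g)
  norms <- sqrt((off[, 1] * voxel_size[1])^2 +
                (off[, 2] * voxel_size[2])^2 +
                (off[, 3] * voxel_size[3])^2)
  keep <- norms <= radius_mm + 1e-9
  structure(off[keep, , drop = FALSE], norms = norms[keep],
            radius_mm = radius_mm, voxel_size = voxel_size,
            class = "structuring_element")
}

# Logical array shifted by integer offset o; voxels whose source falls
# outside the grid become FALSE (outside-grid treated as background).
shift_logical <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
  ys <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
  zs <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
  if (length(xs) < 1L || length(ys) < 1L || length(zs) < 1L) return(out)
  out[xs, ys, zs] <- a[xs + o[1], ys + o[2], zs + o[3]]
  out
}

# Dilation restricted to logical arrays; used internally by the phantom
# generator's distance shells.
dilate_logical <- function(a, offsets) {
  acc <- array(FALSE, dim(a))
  for (r in seq_len(nrow(offsets)))
    acc <- acc | shift_logical(a, offsets[r, ])
  acc
}

#' Morphological erosion with a mm-unit spherical kernel
#'
#' A voxel is retained iff every structuring-element offset lands on a
#' 1-voxel; offsets reaching outside the grid count as 0, so border voxels
#' erode away (conservative: a voxel whose neighborhood cannot be verified
#' is dropped).
#'
#' @param mask A [binary_mask].
#' @param radius_mm Ball radius in mm, or a [structuring_element].
#' @return Eroded [binary_mask] (always a subset of `mask`).
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  se <- if (inherits(radius_mm, "structuring_element")) radius_mm
        else structuring_element(radius_mm, voxel_size(mask))
  a <- mask$data == 1L
  acc <- a
  for (r in seq_len(nrow(se))) {
    o <- se[r, ]
    if (all(o == 0L)) next
    acc <- acc & shift_logical(a, o)
  }
  binary_mask(acc, affine = mask$affine)
}

#' Build the ventricular background ROI for contrast metrics
#'
#' The noise/contrast reference region: the ventricle mask minus the union
#' of all ChP masks, then eroded with a spherical kernel (default 2 mm
#' radius) so that only voxels comfortably inside CSF remain. Operation
#' order is fixed: subtract the union first, then erode.
#'
#' @param ventricles [binary_mask] of the lateral ventricles.
#' @param chp_masks List of [binary_mask]s to exclude (typically the ChP
#'   mask from every sequence); may be empty.
#' @param erosion_radius_mm Kernel radius in mm (default 2).
#' @return [binary_mask]; never intersects any input ChP mask and is a
#'   subset of `ventricles`.
#' @export
build_background_roi <- function(ventricles, chp_masks = list(),
                                 erosion_radius_mm = 2) {
  stopifnot(inherits(ventricles, "binary_mask"), erosion_radius_mm >= 0)
  keep <- ventricles$data == 1L
  for (m in chp_masks) {
    assert_same_geometry(ventricles, m, "ventricle and ChP masks")
    keep <- keep & (m$data == 0L)
  }
  roi <- erode_mask(binary_mask(keep, affine = ventricles$affine),
                    erosion_radius_mm)
  if (voxel_count(roi) == 0L)
    stop("empty background ROI after ", erosion_radius_mm,
         " mm erosion: geometry too small or radius too large")
  roi
}
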