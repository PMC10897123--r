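#' 3D volume with world-space geometry
#'
#' A `volume_image` is a 3D scalar array together with a 4x4 voxel-to-world
#' affine (mm). Voxel sizes are always derived from the affine column norms,
#' never stored independently, so the two cannot disagree.
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform. Defaults to
#'   a diagonal affine built from `voxel_size`.
#' @param voxel_size Length-3 positive voxel dimensions in mm; only used when
#'   `affine` is NULL.
#' @return A `volume_image` object (list with `data` and `affine`).
#' @export
volume_image <- function(data, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " axes")
  if (any(dim(data) < 1L)) stop("every axis must have positive length")
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (!all(is.finite(affine))) stop("affine entries must be finite")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("affine is not invertible")
  structure(list(data = data, affine = affine), class = "volume_image")
}

#' Binary mask
#'
#' A [volume_image] whose voxels are exactly 0 or 1; the unit of all overlap
#' and volume computation.
#'
#' @inheritParams volume_image
#' @return A `binary_mask` object (also a `volume_image`).
#' @export
binary_mask <- function(data, affine = NULL, voxel_size = c(1, 1, 1)) {
  v <- volume_image(data, affine, voxel_size)
  d <- v$data
  if (is.logical(d)) {
    storage.mode(d) <- "integer"
  } else if (!all(d == 0 | d == 1)) {
    stop("mask values must be exactly 0 or 1; use binarize() for soft masks")
  } else {
    storage.mode(d) <- "integer"
  }
  v$data <- d
  class(v) <- c("binary_mask", "volume_image")
  v
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, voxel size %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_size(x), 4), collapse = "x")))
  invisible(x)
}

#' Voxel dimensions in mm
#'
#' Derived from the Euclidean norms of the affine's spatial columns.
#'
#' @param v A [volume_image].
#' @return Numeric length-3 vector (dx, dy, dz) in mm.
#' @export
voxel_size <- function(v) {
  stopifnot(inherits(v, "volume_image"))
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Number of foreground voxels in a mask
#'
#' @param m A [binary_mask].
#' @return Integer count of 1-voxels.
#' @export
voxel_count <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$data)
}

# Shared-geometry predicate used by every pairwise metric.
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$affine - b$affine) <= tol)
}

assert_same_geometry <- function(a, b, what = "masks", tol = 1e-4) {
  if (!same_geometry(a, b, tol))
    stop(what, " do not share grid shape and affine (tol ", tol, ")")
  invisible(TRUE)
}

#' Bundle one subject's co-registered volumes and masks
#'
#' Holds the intensity volume per sequence, the ChP mask per
#' (sequence, rater), and the lateral-ventricle mask, all on one grid.
#' Geometry agreement is checked at construction via
#' [validate_common_space()].
#'
#' @param subject_id Character scalar.
#' @param intensities Named list (sequence -> [volume_image]).
#' @param chp_masks Nested named list (sequence -> rater -> [binary_mask]).
#' @param ventricle_mask [binary_mask] of the lateral ventricles.
#' @param truth_mask Optional [binary_mask] of ground-truth ChP (phantoms).
#' @param tol Affine agreement tolerance in mm (default 1e-4: float32 NIfTI
#'   header rounding).
#' @return A `subject_bundle` object.
#' @export
subject_bundle <- function(subject_id, intensities, chp_masks,
                           ventricle_mask, truth_mask = NULL, tol = 1e-4) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            length(intensities) >= 1L, !is.null(names(intensities)),
            inherits(ventricle_mask, "binary_mask"))
  b <- structure(list(subject_id = subject_id, intensities = intensities,
                      chp_masks = chp_masks, ventricle_mask = ventricle_mask,
                      truth_mask = truth_mask),
                 class = "subject_bundle")
  rep <- validate_common_space(b, tol = tol)
  if (!rep$pass)
    stop("subject ", subject_id, " is not in a common space: ",
         paste(rep$mismatches, collapse = "; "))
  b
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf("<subject_bundle> %s: %d sequence(s), %d ChP mask(s)\n",
              x$subject_id, length(x$intensities),
              sum(lengths(x$chp_masks))))
  invisible(x)
}

# Flatten all member volumes of a bundle into one named list.
bundle_members <- function(bundle) {
  out <- list()
  for (s in names(bundle$intensities))
    out[[paste0("intensity:", s)]] <- bundle$intensities[[s]]
  for (s in names(bundle$chp_masks))
    for (r in names(bundle$chp_masks[[s]]))
      out[[paste0("chp:", s, ":", r)]] <- bundle$chp_masks[[s]][[r]]
  out[["ventricles"]] <- bundle$ventricle_mask
  if (!is.null(bundle$truth_mask)) out[["truth"]] <- bundle$truth_mask
  out
}

#' Check that all members of a bundle share one grid
#'
#' Every downstream metric assumes voxelwise correspondence, so all member
#' volumes must have equal shapes and affines agreeing entrywise within
#' `tol` mm. The first member is the reference.
#'
#' @param bundle A [subject_bundle] (or bare list with the same fields).
#' @param tol Absolute tolerance on affine entries, mm.
#' @return List with `pass` (logical) and `mismatches` (character vector
#'   naming every offending member).
#' @export
validate_common_space <- function(bundle, tol = 1e-4) {
  members <- bundle_members(bundle)
  if (length(members) == 0L) stop("empty bundle")
  ref <- members[[1L]]
  bad <- character(0)
  for (nm in names(members)[-1L]) {
    m <- members[[nm]]
    if (!identical(dim(m$data), dim(ref$data)))
      bad <- c(bad, sprintf("%s: shape (%s) != (%s)", nm,
                            paste(dim(m$data), collapse = ","),
                            paste(dim(ref$data), collapse = ",")))
    else if (!all(abs(m$affine - ref$affine) <= tol))
      bad <- c(bad, sprintf("%s: affine differs by %.3g mm (tol %g)", nm,
                            max(abs(m$affine - ref$affine)), tol))
  }
  list(pass = length(bad) == 0L, mismatches = bad,
       reference = names(members)[1L])
}
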