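#' Read a 3D NIfTI volume
#'
#' Reads NIfTI-1/NIfTI-2 (.nii or .nii.gz). Trailing singleton axes are
#' squeezed; a genuinely 4D image (e.g. a time series) is an error because
#' every pipeline quantity is defined on a single 3D grid.
#'
#' @param path Path to an existing NIfTI file.
#' @return A [volume_image]; voxel sizes come from the affine column norms.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))   # drop niftiImage attributes
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), " axes in ", path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_image(arr, affine = aff)
}

#' Read a NIfTI file as a binary mask
#'
#' Files holding resampled/interpolated masks often carry non-binary values;
#' those are accepted and binarized at 0.5 with a warning.
#'
#' @inheritParams read_volume
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (all(v$data == 0 | v$data == 1)) return(binary_mask(v$data, v$affine))
  warning("non-binary mask file ", basename(path),
          ": binarizing at threshold 0.5")
  binarize(v, 0.5)
}

#' Threshold a volume into a binary mask
#'
#' A voxel maps to 1 iff its value is strictly greater than `threshold`
#' (so a volume equal to the threshold everywhere yields an empty mask).
#' Geometry is preserved.
#'
#' @param v A [volume_image].
#' @param threshold Finite scalar.
#' @return A [binary_mask].
#' @export
binarize <- function(v, threshold = 0.5) {
  stopifnot(inherits(v, "volume_image"), is.finite(threshold))
  binary_mask(v$data > threshold, affine = v$affine)
}

#' Write a volume or mask to NIfTI
#'
#' Masks round-trip bit-exactly; float data to at least 1e-6. The affine is
#' stored in both the sform and qform (code 2).
#'
#' @param v A [volume_image] or [binary_mask].
#' @param path Output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype NIfTI datatype; "auto" picks uint8 for masks, float64
#'   otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "auto") {
  stopifnot(inherits(v, "volume_image"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (identical(datatype, "auto"))
    datatype <- if (inherits(v, "binary_mask")) "uint8" else "double"
  im <- RNifti::asNifti(v$data)
  RNifti::pixdim(im) <- voxel_size(v)
  form <- structure(v$affine, code = 2L)
  im <- RNifti::`sform<-`(im, form)
  im <- RNifti::`qform<-`(im, form)
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}
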