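#' Construct a 3D volume
#'
#' Lightweight container for one 3D image: an intensity array plus voxel
#' size (mm per axis) and a 4x4 affine. The affine defaults to a scaling
#' matrix built from the voxel sizes.
#'
#' @param intensities Numeric 3D array (X x Y x Z), all values finite.
#' @param voxel_size Numeric length-3, mm per axis. Default `c(1, 1, 1)`.
#' @param affine Optional 4x4 spatial transform.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(intensities, voxel_size = c(1, 1, 1), affine = NULL) {
  if (length(dim(intensities)) != 3L)
    abort("`intensities` must be a 3D array")
  if (any(dim(intensities) < 1L)) abort("all volume dimensions must be >= 1")
  stopifnot_finite(intensities, "`intensities`")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) abort("`voxel_size` must be positive")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(
    list(intensities = intensities, voxel_size = voxel_size, affine = affine),
    class = "volume3d"
  )
}

#' @export
dim.volume3d <- function(x) dim(x$intensities)

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x), collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size, collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

as_volume_array <- function(v) {
  if (inherits(v, "volume3d")) v$intensities
  else if (is.array(v) && length(dim(v)) == 3L) v
  else abort("expected a `volume3d` or a 3D array")
}

# Normalized, truncated 1D Gaussian kernel (radius 3 sigma, minimum 1).
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one array axis with zero padding, via a banded matrix
# applied after rotating the target axis to the front.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  B <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    B[lo:hi, j] <- kernel[(lo - j + r + 1L):(hi - j + r + 1L)]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- t(B) %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable convolution with a normalized, truncated (3 sigma) Gaussian
#' kernel and zero padding; the per-axis sigma in voxels is derived from the
#' FWHM in mm and the voxel size.
#'
#' @param v A [volume3d()].
#' @param fwhm_mm Full width at half maximum of the kernel, in mm.
#' @return A smoothed `volume3d`.
#' @export
smooth_volume <- function(v, fwhm_mm) {
  arr <- as_volume_array(v)
  vs <- if (inherits(v, "volume3d")) v$voxel_size else c(1, 1, 1)
  if (fwhm_mm < 0) abort("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(v)
  sig <- fwhm_to_sigma(fwhm_mm) / vs
  for (ax in 1:3) arr <- convolve_axis(arr, gaussian_kernel_1d(sig[ax]), ax)
  volume3d(arr, vs, if (inherits(v, "volume3d")) v$affine else NULL)
}

#' Z-normalize a volume's intensities
#'
#' Centers and scales all voxel intensities to mean 0, sd 1. A constant
#' volume (sd numerically zero) is a degenerate input and raises an error.
#'
#' @param v A [volume3d()] or 3D array.
#' @return A `volume3d` with standardized intensities.
#' @export
znormalize_volume <- function(v) {
  arr <- as_volume_array(v)
  s <- sd(arr)
  if (!is.finite(s) || s < 1e-12)
    abort("degenerate input: constant-intensity volume (sd = 0)")
  arr <- (arr - mean(arr)) / s
  volume3d(arr,
           if (inherits(v, "volume3d")) v$voxel_size else c(1, 1, 1),
           if (inherits(v, "volume3d")) v$affine else NULL)
}

#' Preprocess a volume: optional smoothing, then z-normalization
#'
#' The in-package preprocessing applied after external motion correction
#' and spatial normalization: Gaussian smoothing (skipped when
#' `fwhm_mm = 0`) followed by z-normalization of all voxel intensities.
#' Functional frames are typically smoothed (8 mm FWHM); structural volumes
#' are typically only z-normalized (`fwhm_mm = 0`).
#'
#' @param v A [volume3d()].
#' @param fwhm_mm Smoothing kernel FWHM in mm; `0` disables smoothing.
#' @return A preprocessed `volume3d` with mean 0 and sd 1.
#' @export
preprocess_volume <- function(v, fwhm_mm = 0) {
  znormalize_volume(smooth_volume(v, fwhm_mm))
}

#' Read / write a volume as NIfTI-1
#'
#' Thin wrappers over RNifti. `read_volume()` returns a [volume3d()];
#' `write_volume()` writes one to a `.nii`/`.nii.gz` path.
#'
#' @param path File path.
#' @return `read_volume()`: a `volume3d`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  arr <- array(as.numeric(arr), dim(arr))
  vs <- as.numeric(RNifti::pixdim(img))[1:3]
  volume3d(arr, vs, RNifti::xform(img))
}

#' @rdname read_volume
#' @param v A `volume3d` (for `write_volume()`).
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI series as a list of volumes
#'
#' @param path File path to a 4D NIfTI.
#' @return A list of `volume3d` frames in acquisition order.
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  arr <- array(as.numeric(arr), dim(arr))
  vs <- as.numeric(RNifti::pixdim(img))[1:3]
  lapply(seq_len(dim(arr)[4]), function(t) volume3d(arr[, , , t], vs))
}

#' Write a list of frames as a 4D NIfTI series
#'
#' @param frames List of `volume3d` with identical dimensions.
#' @param path Output path.
#' @export
write_series <- function(frames, path) {
  arrs <- lapply(frames, as_volume_array)
  arr <- array(unlist(arrs), dim = c(dim(arrs[[1]]), length(arrs)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(frames[[1]]$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
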