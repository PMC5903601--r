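#' Number of patch corner positions per axis
#'
#' @param dims Volume dimensions.
#' @param edge Patch edge length.
#' @param stride Corner step in voxels.
#' @return Integer vector of per-axis position counts.
#' @export
patch_grid_dims <- function(dims, edge = 5, stride = 1) {
  if (any(dims < edge)) abort("volume dimension smaller than patch edge")
  vapply(dims, function(d) length(seq.int(1L, d - edge + 1L, by = stride)),
         integer(1))
}

#' Extract overlapping cubic patches from a volume
#'
#' Slides an `edge`^3 cube across the volume with the given stride and
#' flattens each cube into one row (column-major within the cube). With
#' stride 1 this yields one patch per possible corner position, i.e.
#' approximately one patch per voxel. Optionally subsamples uniformly at
#' random (seeded) down to `max_patches` rows.
#'
#' @param v A [volume3d()] or 3D array with every dimension >= `edge`.
#' @param edge Patch edge length (default 5).
#' @param stride Step between patch corners (default 1).
#' @param max_patches Optional cap on the number of rows.
#' @param seed Seed for the subsampling draw.
#' @return A list of class `patch_matrix` with elements `patches`
#'   (m x edge^3 matrix) and `positions` (m x 3 corner coordinates).
#' @export
extract_patches <- function(v, edge = 5, stride = 1,
                            max_patches = NULL, seed = 1) {
  arr <- as_volume_array(v)
  d <- dim(arr)
  g <- patch_grid_dims(d, edge, stride)
  corners <- as.matrix(expand.grid(
    x = seq.int(1L, d[1] - edge + 1L, by = stride),
    y = seq.int(1L, d[2] - edge + 1L, by = stride),
    z = seq.int(1L, d[3] - edge + 1L, by = stride)))
  if (!is.null(max_patches) && nrow(corners) > max_patches) {
    keep <- with_seed(seed, sort(sample.int(nrow(corners), max_patches)))
    corners <- corners[keep, , drop = FALSE]
  }
  off <- as.matrix(expand.grid(dx = 0:(edge - 1), dy = 0:(edge - 1),
                               dz = 0:(edge - 1)))
  lin_off <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  lin_corner <- (corners[, 1] - 1L) + (corners[, 2] - 1L) * d[1] +
    (corners[, 3] - 1L) * d[1] * d[2] + 1L
  idx <- outer(lin_corner, lin_off, `+`)
  patches <- matrix(arr[idx], nrow = nrow(corners))
  structure(list(patches = patches, positions = corners, edge = edge),
            class = "patch_matrix")
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat("<patch_matrix> ", nrow(x$patches), " patches of ",
      x$edge, "^3 = ", ncol(x$patches), " voxels\n", sep = "")
  invisible(x)
}
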