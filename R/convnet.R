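#' Texture-path input transform
#'
#' Z-normalizes a volume and squashes the standardized intensities through
#' the logistic sigmoid into (0, 1). The texture path applies this one
#' transform consistently: filters are learned from patches of the
#' squashed volume and convolved over the same squashed volume, matching
#' the (0, 1) range the sigmoid autoencoder reconstructs.
#'
#' @param v A [volume3d()].
#' @return A `volume3d` with intensities in (0, 1).
#' @export
texture_normalize <- function(v) {
  z <- znormalize_volume(v)
  volume3d(sigmoid(z$intensities), z$voxel_size, z$affine)
}

#' Valid 3D correlation followed by a sigmoid
#'
#' Slides the filter across the volume without padding (output dimensions
#' `dim - filter + 1` per axis), takes the inner product at each position,
#' adds the bias and applies the logistic sigmoid, so every output value
#' lies in (0, 1). The filter is applied as a correlation (no flipping), as
#' is conventional for learned filters.
#'
#' @param v A [volume3d()] or 3D array with dims >= the filter dims.
#' @param f 3D filter array (typically 5 x 5 x 5).
#' @param bias Scalar added before the sigmoid.
#' @return 3D numeric array of sigmoid activations.
#' @export
convolve_sigmoid_3d <- function(v, f, bias = 0) {
  arr <- as_volume_array(v)
  d <- dim(arr); e <- dim(f)
  if (any(d < e)) abort("volume dimensions must be >= filter dimensions")
  od <- d - e + 1L
  out <- array(0, od)
  # accumulate one shifted sub-array per filter tap: cheap and memory-light
  for (dz in seq_len(e[3])) for (dy in seq_len(e[2])) for (dx in seq_len(e[1])) {
    w <- f[dx, dy, dz]
    if (w != 0)
      out <- out + w * arr[dx:(dx + od[1] - 1L),
                           dy:(dy + od[2] - 1L),
                           dz:(dz + od[3] - 1L)]
  }
  sigmoid(out + bias)
}

#' Pooled-grid dimensions
#'
#' Per-axis number of pooling cells. `"ceil"` keeps trailing partial boxes
#' as their own cells (exhaustive tiling); `"round"` reproduces grids
#' obtained by rounding `dim / pool_edge` to the nearest integer, with the
#' final cell cropped or extended to the array boundary.
#'
#' @param dims Input array dimensions.
#' @param pool_edge Pooling box edge length.
#' @param mode `"ceil"` (default) or `"round"`.
#' @return Integer vector of per-axis cell counts.
#' @export
pool_grid_dims <- function(dims, pool_edge = 5, mode = c("ceil", "round")) {
  mode <- match.arg(mode)
  g <- switch(mode,
              ceil = ceiling(dims / pool_edge),
              round = floor(dims / pool_edge + 0.5))
  as.integer(pmax(g, 1L))
}

#' Disjoint 3D max pooling
#'
#' Divides the array into disjoint `pool_edge`^3 boxes and replaces each by
#' its maximum. In the default `"ceil"` mode the tiling is exhaustive:
#' trailing partial boxes form their own cells. In `"round"` mode the grid
#' has `round(dim / pool_edge)` cells per axis and the final cell absorbs
#' (or crops to) the remaining voxels.
#'
#' @param arr 3D numeric array.
#' @param pool_edge Pooling box edge (default 5).
#' @param mode Grid mode, see [pool_grid_dims()].
#' @return 3D array of per-box maxima.
#' @export
max_pool_3d <- function(arr, pool_edge = 5, mode = c("ceil", "round")) {
  mode <- match.arg(mode)
  if (pool_edge < 1) abort("`pool_edge` must be >= 1")
  d <- dim(arr)
  g <- pool_grid_dims(d, pool_edge, mode)
  bounds <- lapply(1:3, function(ax) {
    lo <- (seq_len(g[ax]) - 1L) * pool_edge + 1L
    hi <- pmin(seq_len(g[ax]) * pool_edge, d[ax])
    hi[g[ax]] <- d[ax]                 # last cell extends to the boundary
    lo[g[ax]] <- min(lo[g[ax]], d[ax])
    cbind(lo, hi)
  })
  out <- array(NA_real_, g)
  for (k in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
    out[i, j, k] <- max(arr[bounds[[1]][i, 1]:bounds[[1]][i, 2],
                            bounds[[2]][j, 1]:bounds[[2]][j, 2],
                            bounds[[3]][k, 1]:bounds[[3]][k, 2]])
  }
  out
}

#' Structural texture feature vector
#'
#' Convolves every filter of the bank across the volume
#' ([convolve_sigmoid_3d()]), max-pools each activation map
#' ([max_pool_3d()]) and concatenates the flattened pooled maps in
#' filter-major order. The result has length `k * gx * gy * gz`.
#'
#' @param v A [volume3d()] or 3D array.
#' @param bank A [filter_bank()].
#' @param pool_edge Pooling box edge (default 5).
#' @param mode Pooling grid mode, see [pool_grid_dims()].
#' @return Object of class `texture_features` with `vector`,
#'   `pooled_grid_dims` and `k`.
#' @export
structural_feature_vector <- function(v, bank, pool_edge = 5,
                                      mode = c("ceil", "round")) {
  mode <- match.arg(mode)
  if (bank$k < 1) abort("`bank` must contain at least one filter")
  pooled <- lapply(seq_len(bank$k), function(j) {
    act <- convolve_sigmoid_3d(v, bank$filters[[j]], bank$biases[j])
    max_pool_3d(act, pool_edge, mode)
  })
  g <- dim(pooled[[1]])
  structure(list(vector = unlist(lapply(pooled, as.vector)),
                 pooled_grid_dims = g, k = bank$k),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat("<texture_features> length ", length(x$vector), " = ", x$k, " x (",
      paste(x$pooled_grid_dims, collapse = " x "), ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a filter bank as TSV
#'
#' One row per filter: bias then the flattened weights.
#'
#' @param bank A [filter_bank()].
#' @param path Output path.
#' @export
write_filter_bank <- function(bank, path) {
  m <- do.call(rbind, lapply(seq_len(bank$k), function(j)
    c(bias = bank$biases[j], w = as.numeric(bank$filters[[j]]))))
  readr::write_tsv(as_tibble(as.data.frame(m)), path)
  invisible(path)
}

#' @rdname write_filter_bank
#' @param edge Filter edge length expected in the file.
#' @return `read_filter_bank()`: a `filter_bank`.
#' @export
read_filter_bank <- function(path, edge = 5) {
  m <- as.matrix(readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double())))
  filter_bank(m[, -1, drop = FALSE], m[, 1], edge)
}
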