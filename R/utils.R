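#' Logistic sigmoid
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Convert a Gaussian FWHM to a standard deviation
#'
#' Full width at half maximum relates to the standard deviation of a
#' Gaussian as `fwhm = 2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param fwhm Full width at half maximum (same units as the result).
#' @return Standard deviation.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Moore-Penrose pseudo-inverse via SVD with a relative tolerance.
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Stratified fold assignment: within each class, cycle fold labels over a
# seeded permutation so every fold sees both classes where possible.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Run an expression with a local RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite values"))
}
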