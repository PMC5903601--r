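#' Subject-level PCA of a BOLD series
#'
#' Row-centers the T x V data (each time point's spatial mean removed),
#' eigendecomposes the T x T second-moment (Gram) matrix, and keeps the
#' smallest number of leading eigenvectors whose eigenvalue mass reaches
#' `var_frac` of the total. The reduction operator `U` (T_red x T, rows
#' orthonormal) maps the centered data to the reduced representation
#' `Y = U %*% data_centered`.
#'
#' Working on the T x T Gram matrix rather than the V x V covariance keeps
#' the eigenproblem on the small dimension; the two share nonzero
#' eigenvalues.
#'
#' @param b A [bold_series()] or T x V matrix, T >= 2.
#' @param var_frac Variance fraction to retain (default 0.99).
#' @param center Remove each row's mean before the decomposition
#'   (default `TRUE`); the centering vector is stored so reconstruction is
#'   exact.
#' @return List with `Y` (T_red x V) and `reduction`, a `subject_reduction`
#'   holding `U`, `eigenvalues` (descending, all T), `T_red`,
#'   `var_captured` and `row_center`.
#' @export
subject_pca <- function(b, var_frac = 0.99, center = TRUE) {
  data <- if (inherits(b, "bold_series")) b$data else b
  if (!is.matrix(data) || nrow(data) < 2L) abort("need a T x V matrix, T >= 2")
  rc <- if (center) rowMeans(data) else rep(0, nrow(data))
  Xc <- data - rc
  G <- tcrossprod(Xc)
  eig <- eigen(G, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  if (total <= 0) abort("rank-0 data: all rows constant after centering")
  T_red <- which(cumsum(ev) / total >= var_frac - 1e-12)[1]
  U <- t(eig$vectors[, seq_len(T_red), drop = FALSE])
  red <- structure(list(U = U, eigenvalues = ev, T_red = T_red,
                        var_captured = sum(ev[seq_len(T_red)]) / total,
                        row_center = rc),
                   class = "subject_reduction")
  list(Y = U %*% Xc, reduction = red)
}

#' Group-level PCA of temporally concatenated subject reductions
#'
#' Vertically (temporally) concatenates the subject-level reduced matrices
#' in the given order, then applies the same Gram-matrix PCA to obtain the
#' K x V representative matrix `X = F %*% Y_concat`. `K` is chosen to
#' capture `var_frac` of the concatenated variance, unless `K_fixed`
#' overrides it; if the choice falls below `C_min`, `K` is raised to
#' `C_min` with a warning.
#'
#' @param subject_Ys Ordered list of T_red,i x V matrices (the `Y` from
#'   [subject_pca()]), all sharing V.
#' @param var_frac Variance fraction to retain (default 0.99).
#' @param K_fixed Optional fixed number of retained rows.
#' @param C_min Minimum acceptable K (e.g. a backend's component count).
#' @param center Remove row means of the concatenated matrix first.
#' @return List with `X` (a `representative_matrix`: K x V matrix with a
#'   `group_reduction` attribute) and `reduction`, a `group_reduction`
#'   holding `F`, `blocks` (per-subject row-index ranges into the
#'   concatenated matrix, i.e. column blocks of `F`), `K`, `var_captured`,
#'   `row_center`.
#' @export
group_pca <- function(subject_Ys, var_frac = 0.99, K_fixed = NULL,
                      C_min = NULL, center = TRUE) {
  Vs <- vapply(subject_Ys, ncol, integer(1))
  if (length(unique(Vs)) != 1L) abort("subjects disagree on voxel count V")
  Ycat <- do.call(rbind, subject_Ys)
  rc <- if (center) rowMeans(Ycat) else rep(0, nrow(Ycat))
  Yc <- Ycat - rc
  G <- tcrossprod(Yc)
  eig <- eigen(G, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  if (total <= 0) abort("rank-0 concatenated data")
  K <- if (!is.null(K_fixed)) as.integer(K_fixed)
       else which(cumsum(ev) / total >= var_frac - 1e-12)[1]
  if (!is.null(C_min) && K < C_min) {
    warn(paste0("raising K from ", K, " to requested component count ", C_min))
    K <- as.integer(C_min)
  }
  K <- min(K, nrow(Yc))
  Fmat <- t(eig$vectors[, seq_len(K), drop = FALSE])
  ends <- cumsum(vapply(subject_Ys, nrow, integer(1)))
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- purrr::map2(starts, ends, ~seq.int(.x, .y))
  red <- structure(list(F = Fmat, blocks = blocks, K = K,
                        var_captured = sum(ev[seq_len(K)]) / total,
                        row_center = rc),
                   class = "group_reduction")
  X <- Fmat %*% Yc
  attr(X, "group_reduction") <- red
  class(X) <- c("representative_matrix", class(X))
  list(X = X, reduction = red)
}

#' Back-reconstruct subject-specific component time courses
#'
#' Recovers each subject's T x C time-course matrix from a group-level
#' mixing matrix via the pseudo-inverses of the subject and group
#' reduction operators: `A_i = pinv(U_i) %*% pinv(F)_i %*% A`, where
#' `pinv(F)_i` is the row block of `pinv(F)` belonging to subject i. With
#' orthonormal reduction rows this reverses both PCA steps exactly on
#' noiseless data, so `X^i ~ A_i %*% S`.
#'
#' @param sr The subject's `subject_reduction` (from [subject_pca()]).
#' @param gr The `group_reduction` (from [group_pca()]).
#' @param subject_index Index of the subject within the group ordering.
#' @param A K x C group mixing matrix.
#' @return A T x C matrix of class `subject_timecourses`.
#' @export
back_reconstruct <- function(sr, gr, subject_index, A) {
  if (nrow(A) != gr$K) abort("`A` must have K rows")
  if (subject_index < 1 || subject_index > length(gr$blocks))
    abort("`subject_index` out of range")
  Fdag <- pinv(gr$F)                              # (sum T_red) x K
  Fi_dag <- Fdag[gr$blocks[[subject_index]], , drop = FALSE]
  Ai <- pinv(sr$U) %*% Fi_dag %*% A
  class(Ai) <- c("subject_timecourses", class(Ai))
  Ai
}

#' Flatten subject time courses into a feature vector
#'
#' Component-major (column-major) flattening of the T x C time-course
#' matrix; length T * C.
#'
#' @param tc A `subject_timecourses` (or any T x C matrix).
#' @return Numeric vector of length T * C.
#' @export
fmri_feature_vector <- function(tc) {
  as.numeric(unclass(tc))
}

#' Project a subject's data onto fixed spatial maps
#'
#' Least-squares fit of each time point onto the rows of `S`:
#' `A_i = X_centered %*% pinv(S)`. Used to derive time courses for
#' subjects that were not part of the group decomposition (e.g. holdout
#' scans projected through training-set maps).
#'
#' @param data T x V matrix (or `bold_series`).
#' @param S C x V spatial map matrix.
#' @param center Remove row means first (default `TRUE`).
#' @return T x C `subject_timecourses`.
#' @export
project_timecourses <- function(data, S, center = TRUE) {
  X <- if (inherits(data, "bold_series")) data$data else data
  if (center) X <- X - rowMeans(X)
  Ai <- X %*% pinv(S)
  class(Ai) <- c("subject_timecourses", class(Ai))
  Ai
}
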