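#' Spatial map set
#'
#' `C` shared spatial components over `V` voxels, tagged with the backend
#' that produced them.
#'
#' @param S C x V numeric matrix, rows are spatial maps.
#' @param backend One of `"pca"`, `"kpca"`, `"ica"`, `"nsd"`.
#' @param mask Optional logical 3D mask relating columns to voxels.
#' @return Object of class `spatial_maps`.
#' @export
spatial_maps <- function(S, backend = c("pca", "kpca", "ica", "nsd"),
                         mask = NULL) {
  backend <- match.arg(backend)
  if (!is.matrix(S) || nrow(S) < 1L) abort("`S` must be a C x V matrix")
  stopifnot_finite(S, "`S`")
  structure(list(S = S, backend = backend, mask = mask),
            class = "spatial_maps")
}

#' @export
print.spatial_maps <- function(x, ...) {
  cat("<spatial_maps> ", nrow(x$S), " components x ", ncol(x$S),
      " voxels (backend: ", x$backend, ")\n", sep = "")
  invisible(x)
}

#' Mixing matrix estimate
#'
#' @param A K x C mixing matrix.
#' @return Object of class `mixing_estimate` with `A` and `W = pinv(A)`.
#' @export
mixing_estimate <- function(A) {
  structure(list(A = A, W = pinv(A)), class = "mixing_estimate")
}

#' PCA / identity separation backend
#'
#' Takes the first `C` rows of the representative matrix as the spatial
#' maps (the identity transformation on the group-PCA output); the mixing
#' matrix is the first `C` columns of the K x K identity.
#'
#' @param X K x V representative matrix.
#' @param C Number of components, `C <= K`.
#' @return List with `maps` ([spatial_maps()]) and `mixing`
#'   ([mixing_estimate()]).
#' @export
separate_pca <- function(X, C) {
  K <- nrow(X)
  if (C > K) abort("`C` must be <= K")
  S <- unclass(X)[seq_len(C), , drop = FALSE]
  attr(S, "group_reduction") <- NULL
  A <- diag(K)[, seq_len(C), drop = FALSE]
  list(maps = spatial_maps(S, "pca"), mixing = mixing_estimate(A))
}

#' RBF kernel PCA separation backend
#'
#' Builds the radial-basis-function kernel over the voxel columns of `X`,
#' `k(i, j) = exp(-||x_i - x_j||^2 / (2 sigma^2))`, double-centers it, and
#' takes the top `C` eigenvectors as spatial maps (each scaled by the
#' square root of its eigenvalue). The mixing matrix is the least-squares
#' projection of `X` onto the maps. The V x V kernel restricts this
#' backend to modest voxel counts; `max_voxels` guards against accidental
#' full-brain use.
#'
#' @param X K x V representative matrix.
#' @param sigma Kernel width, > 0.
#' @param C Number of components.
#' @param max_voxels Guard on V (default 5000).
#' @return List with `maps`, `mixing` and `eigenvalues`.
#' @export
separate_kpca <- function(X, sigma, C, max_voxels = 5000) {
  Xm <- unclass(X)
  V <- ncol(Xm)
  if (V > max_voxels)
    abort(paste0("V = ", V, " exceeds the kernel-PCA guard (", max_voxels,
                 " voxels); raise `max_voxels` only if a V x V matrix fits"))
  if (sigma <= 0) abort("`sigma` must be > 0")
  sq <- colSums(Xm^2)
  D2 <- outer(sq, sq, `+`) - 2 * crossprod(Xm)
  D2[D2 < 0] <- 0
  Kmat <- exp(-D2 / (2 * sigma^2))
  rm_ <- rowMeans(Kmat)                 # symmetric: row means = col means
  Kc <- sweep(sweep(Kmat, 1, rm_), 2, rm_) + mean(Kmat)
  eig <- eigen(Kc, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
    abort("centered kernel is not positive semi-definite")
  if (C > V) abort("`C` must be <= V")
  lam <- pmax(eig$values[seq_len(C)], 0)
  S <- t(eig$vectors[, seq_len(C), drop = FALSE]) * sqrt(lam)
  A <- Xm %*% t(S) %*% solve(tcrossprod(S) + 1e-12 * diag(C))
  list(maps = spatial_maps(S, "kpca"), mixing = mixing_estimate(A),
       eigenvalues = eig$values)
}

#' Maximum-likelihood ICA with a Laplacian source prior
#'
#' Decomposes `X ~ A S` into spatially independent maps by maximizing the
#' data log-likelihood under unit-scale Laplacian source densities,
#' `sum_h sum_j log p(w_h' x_j) + V log |det W|`, via natural-gradient
#' ascent with an annealed step size on internally whitened data. The
#' source scale is fixed to one after whitening; scale indeterminacy is
#' absorbed into the mixing matrix. Components are ordered by descending
#' spatial-map variance and signed so each map's largest-magnitude entry is
#' positive.
#'
#' @param X K x V representative matrix.
#' @param C Number of components, `C <= K`.
#' @param seed RNG seed (the algorithm is deterministic given the seed).
#' @param max_epochs Iteration cap (default 1000).
#' @param step0 Initial natural-gradient step (default 0.2).
#' @param tol Relative log-likelihood improvement for convergence.
#' @return List with `maps`, `mixing`, `loglik_trace` and `converged`.
#' @export
separate_ica <- function(X, C = nrow(X), seed = 1, max_epochs = 1000,
                         step0 = 0.2, tol = 1e-9) {
  Xm <- unclass(X)
  K <- nrow(Xm); V <- ncol(Xm)
  if (C > K) abort("`C` must be <= K")
  # whiten: project to top-C principal directions, unit covariance
  Cv <- tcrossprod(Xm) / V
  eig <- eigen(Cv, symmetric = TRUE)
  ev <- pmax(eig$values[seq_len(C)], 1e-12)
  Wh <- (1 / sqrt(ev)) * t(eig$vectors[, seq_len(C), drop = FALSE])  # C x K
  Z <- Wh %*% Xm
  W <- diag(C)
  loglik <- function(W) {
    Y <- W %*% Z
    -sum(abs(Y)) + V * determinant(W)$modulus[1]
  }
  ll <- loglik(W)
  if (!is.finite(ll)) abort("non-finite initial likelihood")
  trace <- ll
  eta <- step0
  converged <- FALSE
  for (it in seq_len(max_epochs)) {
    Y <- W %*% Z
    G <- (diag(C) - tcrossprod(sign(Y), Y) / V) %*% W   # natural gradient
    accepted <- FALSE
    while (eta > 1e-12) {
      W_new <- W + eta * G
      ll_new <- loglik(W_new)
      if (is.finite(ll_new) && ll_new >= ll) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break                                # step underflow
    improve <- ll_new - ll
    W <- W_new; ll <- ll_new
    trace <- c(trace, ll)
    eta <- min(eta * 1.2, step0)
    if (improve < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  W_orig <- W %*% Wh                                    # C x K unmixing
  S <- W_orig %*% Xm
  ord <- order(apply(S, 1, var), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  W_orig <- W_orig[ord, , drop = FALSE]
  sgn <- vapply(seq_len(C), function(h) {
    s <- sign(S[h, which.max(abs(S[h, ]))]); if (s == 0) 1 else s
  }, numeric(1))
  S <- S * sgn
  W_orig <- W_orig * sgn
  A <- pinv(W_orig)                                     # K x C
  out <- list(maps = spatial_maps(S, "ica"),
              mixing = mixing_estimate(A),
              unmixing = W_orig,
              loglik_trace = trace, converged = converged)
  out
}

#' Amari separation index
#'
#' Permutation- and scale-invariant measure of how close a gain matrix is
#' to a scaled permutation; 0 iff perfect separation, bounded by 1.
#'
#' @param G Square gain matrix, e.g. `W_est %*% A_true`.
#' @return Scalar in `[0, 1]`.
#' @export
amari_index <- function(G) {
  G <- abs(G)
  C <- nrow(G)
  if (C != ncol(G)) abort("`G` must be square")
  r <- sum(rowSums(G) / apply(G, 1, max) - 1)
  c <- sum(colSums(G) / apply(G, 2, max) - 1)
  (r + c) / (2 * C * (C - 1))
}

#' Align estimated components with reference components
#'
#' Finds the one-to-one assignment maximizing the total absolute
#' correlation between estimated and reference spatial maps (exhaustively
#' for C <= 7, greedily above), together with the matched signs, the
#' per-component correlations, and the Amari index of the induced gain
#' matrix `S_est %*% pinv(S_true)`.
#'
#' @param S_est,S_true C x V matrices (or [spatial_maps()]) of equal shape.
#' @return List with `permutation` (est index for each true component),
#'   `signs`, `correlations` (absolute, per matched pair) and
#'   `amari_index`.
#' @export
align_components <- function(S_est, S_true) {
  if (inherits(S_est, "spatial_maps")) S_est <- S_est$S
  if (inherits(S_true, "spatial_maps")) S_true <- S_true$S
  if (!all(dim(S_est) == dim(S_true))) abort("shapes must match")
  C <- nrow(S_est)
  if (any(apply(S_est, 1, sd) < 1e-14) || any(apply(S_true, 1, sd) < 1e-14))
    abort("zero-variance component")
  R <- cor(t(S_true), t(S_est))               # true x est
  absR <- abs(R)
  if (C <= 7) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(C)), C)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == C), ,
                   drop = FALSE]
    scores <- apply(perms, 1, function(p) sum(absR[cbind(seq_len(C), p)]))
    perm <- as.integer(perms[which.max(scores), ])
  } else {
    perm <- integer(C); used <- logical(C)
    tmp <- absR
    for (step in seq_len(C)) {
      best <- which(tmp == max(tmp), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      tmp[best[1], ] <- -Inf; tmp[, best[2]] <- -Inf
    }
  }
  corrs <- absR[cbind(seq_len(C), perm)]
  signs <- sign(R[cbind(seq_len(C), perm)])
  signs[signs == 0] <- 1
  G <- S_est %*% pinv(S_true)
  list(permutation = perm, signs = signs, correlations = corrs,
       amari_index = amari_index(G))
}
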