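#' Local second-moment field of a representative matrix
#'
#' Tiles the mask into disjoint `box_edge`^3 regions (trailing partial
#' boxes kept) and, for each region, forms the K x K second moment of the
#' voxel columns falling inside it:
#' `R_hat(r) = (1 / |N(r)|) * sum_{v in N(r)} x_v x_v'`.
#' No mean removal by default (`center = TRUE` subtracts the per-region
#' column mean first). Regions containing no mask voxels are dropped.
#'
#' @param X K x V matrix whose columns correspond, in scan order, to the
#'   `TRUE` voxels of `mask`.
#' @param mask Logical 3D array with V `TRUE` voxels.
#' @param box_edge Region edge length (default 4).
#' @param center Subtract the per-region mean before the outer products.
#' @return Object of class `local_cov_field`: list with `R` (list of K x K
#'   symmetric matrices), `regions` (voxel-column index sets), `corners`
#'   and `K`.
#' @export
local_covariances <- function(X, mask, box_edge = 4, center = FALSE) {
  Xm <- unclass(X)
  if (!is.logical(mask)) mask <- mask != 0
  if (sum(mask) != ncol(Xm)) abort("mask voxel count must equal ncol(X)")
  if (box_edge < 1) abort("`box_edge` must be >= 1")
  d <- dim(mask)
  col_of <- array(NA_integer_, d)
  col_of[which(mask)] <- seq_len(ncol(Xm))
  g <- ceiling(d / box_edge)
  R <- list(); regions <- list(); corners <- list()
  for (k in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
    xr <- ((i - 1) * box_edge + 1):min(i * box_edge, d[1])
    yr <- ((j - 1) * box_edge + 1):min(j * box_edge, d[2])
    zr <- ((k - 1) * box_edge + 1):min(k * box_edge, d[3])
    cols <- col_of[xr, yr, zr]
    cols <- cols[!is.na(cols)]
    if (length(cols) == 0) next
    Xr <- Xm[, cols, drop = FALSE]
    if (center) Xr <- Xr - rowMeans(Xr)
    R[[length(R) + 1L]] <- tcrossprod(Xr) / length(cols)
    regions[[length(regions) + 1L]] <- cols
    corners[[length(corners) + 1L]] <- c(xr[1], yr[1], zr[1])
  }
  local_cov_field(R, regions, corners)
}

#' Construct a local covariance field directly
#'
#' @param R List of K x K symmetric PSD matrices.
#' @param regions Optional list of voxel-column index sets.
#' @param corners Optional list of region corner coordinates.
#' @return A `local_cov_field`.
#' @export
local_cov_field <- function(R, regions = NULL, corners = NULL) {
  K <- nrow(R[[1]])
  for (Rk in R) {
    if (!all(dim(Rk) == K)) abort("all region matrices must be K x K")
    if (max(abs(Rk - t(Rk))) > 1e-8 * max(abs(Rk), 1))
      abort("region matrix is not symmetric")
  }
  structure(list(R = R, regions = regions, corners = corners, K = K,
                 n_regions = length(R)),
            class = "local_cov_field")
}

#' @export
print.local_cov_field <- function(x, ...) {
  cat("<local_cov_field> ", x$n_regions, " regions of ", x$K, " x ", x$K,
      " second moments\n", sep = "")
  invisible(x)
}

nsd_objective <- function(A, D, R) {
  obj <- 0
  for (k in seq_along(R)) {
    E <- R[[k]] - A %*% (D[k, ] * t(A))
    obj <- obj + sum(E^2)
  }
  obj
}

nsd_gradient_A <- function(A, D, R) {
  G <- matrix(0, nrow(A), ncol(A))
  for (k in seq_along(R)) {
    E <- R[[k]] - A %*% (D[k, ] * t(A))
    G <- G - 4 * E %*% A %*% diag(D[k, ], ncol(A))
  }
  G
}

#' Fit a non-stationary spatial source decomposition
#'
#' Estimates a single mixing matrix `A` (K x C, unit-norm columns) and
#' per-region nonnegative diagonal source powers `D(r)` minimizing the
#' covariance-matching objective
#' `sum_k || R_hat(r_k) - A D(r_k) A' ||_F^2`
#' by alternating minimization:
#' \itemize{
#'   \item D-step: for each region, nonnegative least squares of
#'     `vec(R_hat(r_k))` on the columns `vec(a_c a_c')`;
#'   \item A-step: quasi-Newton (L-BFGS-B) descent on the summed objective
#'     with the analytic gradient, accepted only if it does not increase
#'     the objective;
#'   \item column renormalization: columns of `A` scaled to unit norm with
#'     the scale absorbed into the `D(r)`.
#' }
#' `A` is initialized from the top-C eigenvectors of the mean region
#' matrix; additional seeded random orthonormal starts (`n_starts > 1`)
#' guard against local minima of the non-convex objective, keeping the
#' start with the lowest final objective. The per-sweep objective trace is
#' non-increasing by construction. Sources whose variance profile varies
#' across regions are identifiable from these second-order statistics
#' alone; a stationary field (all `D(r)` equal) leaves a rotation
#' indeterminacy.
#'
#' @param field A [local_cov_field()] with at least 2 regions.
#' @param C Number of components, `C <= K` (default K).
#' @param seed RNG seed for the random restarts.
#' @param tol Relative objective decrease for convergence (default 1e-6).
#' @param max_sweeps Sweep cap (default 500).
#' @param inner_iter A-step iteration cap per sweep (default 50).
#' @param n_starts Number of initializations (default 1: eigenvector init
#'   only).
#' @param polish After the alternating phase, refine (A, D) jointly with a
#'   bounded quasi-Newton step (default `TRUE`). Alternating updates can
#'   crawl along ill-conditioned valleys; the joint step restores fast
#'   local convergence and is accepted only if it lowers the objective.
#' @return Object of class `nsd_model` with `A`, `D` (n_regions x C
#'   matrix), `objective_trace`, `converged`, `K`, `C`.
#' @export
fit_nsd <- function(field, C = field$K, seed = 1, tol = 1e-6,
                    max_sweeps = 500, inner_iter = 50, n_starts = 1,
                    polish = TRUE) {
  R <- field$R
  K <- field$K
  N <- length(R)
  if (N < 2) abort("need at least 2 regions")
  if (C > K) abort("`C` must be <= K")
  Rmean <- Reduce(`+`, R) / N
  if (max(abs(Rmean)) < 1e-14) abort("degenerate input: all-zero field")
  best <- NULL
  for (start in seq_len(n_starts)) {
    A0 <- if (start == 1)
      eigen(Rmean, symmetric = TRUE)$vectors[, seq_len(C), drop = FALSE]
    else
      with_seed(seed + start,
                qr.Q(qr(matrix(rnorm(K * C), K, C))))
    fit <- nsd_fit_one(A0, R, K, C, N, tol, max_sweeps, inner_iter)
    if (is.null(best) ||
        fit$objective_trace[length(fit$objective_trace)] <
          best$objective_trace[length(best$objective_trace)])
      best <- fit
  }
  if (polish) best <- nsd_polish(best, R, K, C, N, tol)
  structure(c(best, list(K = K, C = C)), class = "nsd_model")
}

# Joint bounded quasi-Newton refinement over (A, D): fast local
# convergence where the alternating scheme zigzags. Monotone by
# construction (kept only on improvement).
nsd_polish <- function(fit, R, K, C, N, tol, maxit = 500) {
  obj0 <- fit$objective_trace[length(fit$objective_trace)]
  par0 <- c(as.numeric(fit$A), as.numeric(fit$D))
  unpack <- function(par) list(A = matrix(par[seq_len(K * C)], K, C),
                               D = matrix(par[-seq_len(K * C)], N, C))
  fn <- function(par) {
    p <- unpack(par)
    nsd_objective(p$A, p$D, R)
  }
  gr <- function(par) {
    p <- unpack(par)
    gA <- matrix(0, K, C); gD <- matrix(0, N, C)
    for (k in seq_len(N)) {
      E <- R[[k]] - p$A %*% (p$D[k, ] * t(p$A))
      gA <- gA - 4 * E %*% p$A %*% diag(p$D[k, ], C)
      gD[k, ] <- -2 * colSums((E %*% p$A) * p$A)
    }
    c(as.numeric(gA), as.numeric(gD))
  }
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               lower = c(rep(-Inf, K * C), rep(0, N * C)),
               control = list(maxit = maxit, factr = 10))
  if (opt$value < obj0) {
    p <- unpack(opt$par)
    nrm <- sqrt(colSums(p$A^2)); nrm[nrm < 1e-14] <- 1
    fit$A <- sweep(p$A, 2, nrm, `/`)
    fit$D <- sweep(p$D, 2, nrm^2, `*`)
    fit$objective_trace <- c(fit$objective_trace,
                             nsd_objective(fit$A, fit$D, R))
    rel0 <- (obj0 - opt$value) / max(obj0, .Machine$double.eps)
    if (opt$convergence == 0 || rel0 < tol) fit$converged <- TRUE
  }
  fit
}

nsd_fit_one <- function(A, R, K, C, N, tol, max_sweeps, inner_iter) {
  d_step <- function(A) {
    M <- sapply(seq_len(C), function(c) as.numeric(tcrossprod(A[, c])))
    matrix(t(sapply(seq_len(N), function(k)
      pracma::lsqnonneg(M, as.numeric(R[[k]]))$x)), N, C)
  }
  D <- d_step(A)
  obj <- nsd_objective(A, D, R)
  trace <- obj
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    # A-step: bounded quasi-Newton on vec(A), D fixed
    fn <- function(a) nsd_objective(matrix(a, K, C), D, R)
    gr <- function(a) as.numeric(nsd_gradient_A(matrix(a, K, C), D, R))
    fit <- optim(as.numeric(A), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = inner_iter))
    if (fit$value <= obj) A <- matrix(fit$par, K, C)
    # renormalize columns, absorb scale into D
    nrm <- sqrt(colSums(A^2))
    nrm[nrm < 1e-14] <- 1
    A <- sweep(A, 2, nrm, `/`)
    D <- sweep(D, 2, nrm^2, `*`)
    # D-step (exact given A)
    D <- d_step(A)
    obj_new <- nsd_objective(A, D, R)
    if (obj_new > obj + 1e-12 * max(obj, 1))
      abort("internal error: objective increased across a sweep")
    trace <- c(trace, obj_new)
    rel <- (obj - obj_new) / max(obj, .Machine$double.eps)
    obj <- obj_new
    if (rel < tol) { converged <- TRUE; break }
  }
  list(A = A, D = D, objective_trace = trace, converged = converged)
}

#' @export
print.nsd_model <- function(x, ...) {
  cat("<nsd_model> K = ", x$K, ", C = ", x$C, ", ", length(x$objective_trace),
      " sweeps, final objective ", format(x$objective_trace[length(x$objective_trace)],
                                          digits = 4),
      if (x$converged) " (converged)\n" else " (not converged)\n", sep = "")
  invisible(x)
}

#' Extract spatial sources under a fitted NSD model
#'
#' Columnwise least squares `s_hat = argmin_s ||x - A s||^2`, i.e.
#' `S = pinv(A) %*% X`; the residual `X - A S` is orthogonal to the column
#' space of `A`. A rank-deficient `A` yields the minimum-norm solution
#' with a warning.
#'
#' @param X K x V representative matrix.
#' @param model A fitted [fit_nsd()] model.
#' @param force Proceed even if the model did not converge.
#' @return A [spatial_maps()] with backend `"nsd"`.
#' @export
extract_nsd_sources <- function(X, model, force = FALSE) {
  if (!model$converged && !force)
    abort("model did not converge; pass force = TRUE to extract anyway")
  Xm <- unclass(X)
  A <- model$A
  if (qr(A)$rank < ncol(A))
    warn("rank-deficient mixing matrix: returning the minimum-norm solution")
  S <- pinv(A) %*% Xm
  spatial_maps(S, "nsd")
}
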