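# Shared fixture builders; everything is generated in code, seeded.

random_volume <- function(dims = c(8, 8, 8), seed = 1, voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  volume3d(array(rnorm(prod(dims)), dims), voxel_size)
}

# C x V matrix with orthonormal, zero-mean rows (exact-model source maps)
orthonormal_sources <- function(C, V, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(C * V), C, V)
  M <- M - rowMeans(M)
  S <- t(qr.Q(qr(t(M))))
  S <- S - rowMeans(S)
  t(qr.Q(qr(t(S))))
}

# noiseless cohort X^i = A_i S over orthonormal zero-mean sources
exact_model_cohort <- function(n = 5, Tn = 12, C = 3, V = 400, seed = 1) {
  S <- orthonormal_sources(C, V, seed)
  set.seed(seed + 1)
  A_true <- lapply(seq_len(n), function(i) matrix(rnorm(Tn * C), Tn, C))
  list(S = S, A_true = A_true,
       data = lapply(A_true, function(A) A %*% S))
}

# cohort tibble on disk for load_cohort tests
write_test_cohort_tsv <- function(rows, dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  for (p in unique(c(rows$structural_path, rows$functional_path))) {
    if (nzchar(p)) file.create(file.path(dir, p))
  }
  rows$structural_path <- ifelse(nzchar(rows$structural_path),
                                 file.path(dir, rows$structural_path), "")
  rows$functional_path <- ifelse(nzchar(rows$functional_path),
                                 file.path(dir, rows$functional_path), "")
  path <- file.path(dir, "cohort.tsv")
  readr::write_tsv(rows, path)
  path
}

# direct triple-loop correlation + sigmoid (independent oracle)
naive_convolve_sigmoid <- function(arr, f, bias) {
  d <- dim(arr); e <- dim(f)
  od <- d - e + 1L
  out <- array(NA_real_, od)
  for (z in seq_len(od[3])) for (y in seq_len(od[2])) for (x in seq_len(od[1])) {
    s <- 0
    for (dz in seq_len(e[3])) for (dy in seq_len(e[2])) for (dx in seq_len(e[1]))
      s <- s + arr[x + dx - 1, y + dy - 1, z + dz - 1] * f[dx, dy, dz]
    out[x, y, z] <- 1 / (1 + exp(-(s + bias)))
  }
  out
}

# brute-force max pooling by explicit voxel enumeration (independent oracle)
naive_max_pool <- function(arr, p, g) {
  d <- dim(arr)
  out <- array(NA_real_, g)
  for (k in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
    xs <- ((i - 1) * p + 1):(if (i == g[1]) d[1] else i * p)
    ys <- ((j - 1) * p + 1):(if (j == g[2]) d[2] else j * p)
    zs <- ((k - 1) * p + 1):(if (k == g[3]) d[3] else k * p)
    out[i, j, k] <- max(arr[xs, ys, zs])
  }
  out
}

# central finite differences of the autoencoder objective
ae_fd_gradient <- function(params, D, h = 1e-6) {
  flat <- brainsep:::ae_flatten(params)
  vapply(seq_along(flat), function(i) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    pu <- brainsep:::ae_unflatten(up, params$k, params$n, params$rho,
                                  params$beta, params$lambda)
    pd <- brainsep:::ae_unflatten(dn, params$k, params$n, params$rho,
                                  params$beta, params$lambda)
    (ae_objective(pu, D)$objective - ae_objective(pd, D)$objective) / (2 * h)
  }, numeric(1))
}

random_ae_params <- function(n, k, seed, rho = 0.05, beta = 0.7, lambda = 1e-3) {
  set.seed(seed)
  ae_params(matrix(rnorm(k * n, sd = 0.5), k, n), rnorm(k, sd = 0.3),
            matrix(rnorm(n * k, sd = 0.5), n, k), rnorm(n, sd = 0.3),
            rho = rho, beta = beta, lambda = lambda)
}

# Mixtures distinguishable only by regional variance profiles: uniform
# (sub-Gaussian) sources with complementary two-level variance fields
# constant on box^3 tiles. Both sources share the same marginal scale
# mixture, and its sub-Gaussian shape carries no usable signal for a
# super-Gaussian-prior stationary ICA, so only the regional second-order
# structure distinguishes the sources.
regional_variance_mixture <- function(seed, ratio = 1.4, d = c(24, 24, 16),
                                      box = 8, C = 2) {
  set.seed(seed)
  V <- prod(d)
  bg <- ceiling(d / box)
  bx <- (seq_len(d[1]) - 1L) %/% box
  by <- (seq_len(d[2]) - 1L) %/% box
  bz <- (seq_len(d[3]) - 1L) %/% box
  box_id <- outer(outer(bx, by * bg[1], `+`), bz * bg[1] * bg[2], `+`)
  owner <- (as.vector(box_id) %% C) + 1L
  sds <- matrix(1, C, V)
  for (h in seq_len(C)) sds[h, owner == h] <- ratio
  S <- matrix(runif(C * V, -sqrt(3), sqrt(3)), C, V) * sds
  A <- matrix(rnorm(C * C), C, C)
  list(X = A %*% S, A = A, S = S, mask = array(TRUE, d), box = box)
}

# paired Amari indices of the NSD and stationary-ICA fits on one mixture
nsd_vs_ica_amari <- function(seed, ...) {
  mix <- regional_variance_mixture(seed, ...)
  ica <- separate_ica(mix$X, nrow(mix$A), seed = seed)
  field <- local_covariances(mix$X, mix$mask, box_edge = mix$box)
  m <- fit_nsd(field, nrow(mix$A), seed = seed, tol = 1e-8,
               max_sweeps = 200, n_starts = 3)
  c(nsd = amari_index(MASS::ginv(m$A) %*% mix$A),
    ica = amari_index(ica$unmixing %*% mix$A))
}
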