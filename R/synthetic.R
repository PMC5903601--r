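#' Synthetic cohort specification
#'
#' Desk-scale study conditions for the seeded generators: grid dimensions,
#' series length, true component count, the box tiling of the
#' location-dependent Laplacian scale fields, group effect size (in sd
#' units of the time-course weights), site structure and additive noise.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param dims Volume grid (default `c(20, 20, 12)`).
#' @param t_len Time points per subject (default 60).
#' @param C_true Number of true shared sources (default 4).
#' @param box_edge Edge of the piecewise-constant scale-field boxes,
#'   matching the region tiling used by the decomposition (default 4).
#' @param lambda_active,lambda_background Laplacian rate inside a
#'   component's active boxes vs elsewhere (variance is `2 / lambda^2`, so
#'   smaller rates mean stronger sources). Defaults 0.5 and 2.
#' @param effect_size Group mean shift, in sd units, applied to the case
#'   group on the affected components (default 1.5).
#' @param n_effect_components How many components carry the group effect
#'   (default 2).
#' @param n_sites Number of acquisition sites (default 2).
#' @param site_offset Sd of the per-site additive offset on the
#'   time-course weights (default 0.5).
#' @param noise_sd Sd of the i.i.d. Gaussian measurement noise added to
#'   the voxel data (default 0.1).
#' @param train_frac Fraction of subjects assigned to the training split.
#' @param seed Generator seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 20, dims = c(20, 20, 12),
                           t_len = 60, C_true = 4, box_edge = 4,
                           lambda_active = 0.5, lambda_background = 2,
                           effect_size = 1.5, n_effect_components = 2,
                           n_sites = 2, site_offset = 0.5, noise_sd = 0.1,
                           train_frac = 0.7, seed = 1) {
  spec <- list(n_subjects = n_subjects, dims = dims, t_len = t_len,
               C_true = C_true, box_edge = box_edge,
               lambda_active = lambda_active,
               lambda_background = lambda_background,
               effect_size = effect_size,
               n_effect_components = min(n_effect_components, C_true),
               n_sites = n_sites, site_offset = site_offset,
               noise_sd = noise_sd, train_frac = train_frac, seed = seed)
  if (any(unlist(spec[c("n_subjects", "dims", "t_len", "C_true",
                        "box_edge", "n_sites")]) < 1))
    abort("all counts must be >= 1")
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  structure(spec, class = "synthetic_spec")
}

rlaplace <- function(n, rate) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / rate
}

#' Simulate non-stationary spatial sources
#'
#' Draws `C_true` spatial maps over the full grid. Each component has a
#' piecewise-constant Laplacian rate field on the `box_edge`^3 tiling:
#' boxes are assigned round-robin to components, and a component's voxel
#' values are Laplacian with rate `lambda_active` inside its own boxes and
#' `lambda_background` elsewhere, so components differ in where their
#' variance concentrates. Reproducible per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `S_true` (C x V matrix, columns in scan order over
#'   the full-grid mask), `lambda_fields` (C x V matrix of rates) and
#'   `mask` (all-`TRUE` 3D array).
#' @export
simulate_nonstationary_sources <- function(spec) {
  d <- spec$dims
  V <- prod(d)
  C <- spec$C_true
  mask <- array(TRUE, d)
  # box id per voxel on the same tiling local_covariances() uses
  bg <- ceiling(d / spec$box_edge)
  bx <- (seq_len(d[1]) - 1L) %/% spec$box_edge
  by <- (seq_len(d[2]) - 1L) %/% spec$box_edge
  bz <- (seq_len(d[3]) - 1L) %/% spec$box_edge
  box_id <- outer(outer(bx, by * bg[1], `+`), bz * bg[1] * bg[2], `+`)
  owner <- (as.vector(box_id) %% C) + 1L           # round-robin ownership
  lambda_fields <- matrix(spec$lambda_background, C, V)
  for (h in seq_len(C)) lambda_fields[h, owner == h] <- spec$lambda_active
  S <- with_seed(spec$seed, {
    t(vapply(seq_len(C), function(h) rlaplace(V, lambda_fields[h, ]),
             numeric(V)))
  })
  list(S_true = S, lambda_fields = lambda_fields, mask = mask)
}

#' Simulate a functional cohort over shared sources
#'
#' Each subject's T x C true time-course matrix has i.i.d. standard normal
#' entries; the case group's mean is shifted by `-effect_size` on the
#' first `n_effect_components` components; each site contributes a
#' per-component additive offset drawn once with sd `site_offset`; the
#' observed data are `A_i %*% S_true` plus i.i.d. Gaussian noise of sd
#' `noise_sd`. Labels alternate case/control, sites cycle, and the
#' train/holdout split is stratified by label.
#'
#' @param spec A [synthetic_spec()].
#' @param S_true C x V source matrix (from
#'   [simulate_nonstationary_sources()]).
#' @return List with `series` (list of [bold_series()]), `A_true` (list of
#'   T x C matrices), `cohort` (tibble) and `mask`.
#' @export
simulate_fmri_cohort <- function(spec, S_true) {
  if (nrow(S_true) != spec$C_true) abort("S_true rows must equal C_true")
  d <- spec$dims
  V <- prod(d)
  if (ncol(S_true) != V) abort("S_true columns must match the grid")
  mask <- array(TRUE, d)
  n <- spec$n_subjects
  labels <- rep(c("case", "control"), length.out = n)
  # contiguous site blocks so alternating labels stay balanced within site
  sites <- paste0("site", ((seq_len(n) - 1L) * spec$n_sites) %/% n + 1L)
  eff <- seq_len(spec$n_effect_components)
  with_seed(spec$seed + 1L, {
    site_shift <- matrix(rnorm(spec$n_sites * spec$C_true,
                               sd = spec$site_offset),
                         spec$n_sites, spec$C_true)
    A_true <- vector("list", n)
    series <- vector("list", n)
    for (i in seq_len(n)) {
      A <- matrix(rnorm(spec$t_len * spec$C_true), spec$t_len, spec$C_true)
      if (labels[i] == "case")
        A[, eff] <- A[, eff] - spec$effect_size
      s_idx <- as.integer(sub("site", "", sites[i]))
      A <- A + matrix(site_shift[s_idx, ], spec$t_len, spec$C_true,
                      byrow = TRUE)
      X <- A %*% S_true
      if (spec$noise_sd > 0)
        X <- X + matrix(rnorm(length(X), sd = spec$noise_sd), nrow(X))
      A_true[[i]] <- A
      series[[i]] <- bold_series(X, mask,
                                 subject_id = sprintf("sub%03d", i),
                                 site = sites[i], label = labels[i])
    }
    split <- rep("holdout", n)
    for (cl in c("case", "control")) {
      idx <- which(labels == cl)
      split[idx[seq_len(round(spec$train_frac * length(idx)))]] <- "train"
    }
    cohort <- validate_cohort(tibble(
      subject_id = sprintf("sub%03d", seq_len(n)), label = labels,
      site = sites, split = split,
      structural_path = "", functional_path = ""))
    list(series = series, A_true = A_true, cohort = cohort, mask = mask)
  })
}

#' Simulate a structural cohort with group-dependent texture
#'
#' Volumes are a shared smooth background (low-frequency field) plus
#' subject-specific smooth variation plus fine-grained voxel noise; in the
#' case group the fine-grained texture inside a central region has its
#' amplitude raised by `contrast` sd units, emulating a group difference
#' in texture statistics without any difference in gross anatomy. Seeded
#' and fully reproducible.
#'
#' @param spec A [synthetic_spec()]; `effect_size` is reused as the
#'   default texture contrast.
#' @param contrast Texture amplitude difference in sd units (default
#'   `spec$effect_size`).
#' @return List with `volumes` (list of [volume3d()]) and `cohort`.
#' @export
simulate_structural_cohort <- function(spec, contrast = spec$effect_size) {
  d <- spec$dims
  n <- spec$n_subjects
  labels <- rep(c("case", "control"), length.out = n)
  sites <- paste0("site", ((seq_len(n) - 1L) * spec$n_sites) %/% n + 1L)
  ctr <- lapply(d, function(m) max(1, floor(m / 4)):min(m, ceiling(3 * m / 4)))
  with_seed(spec$seed + 2L, {
    background <- array(rnorm(prod(d)), d)
    background <- smooth_volume(volume3d(background), 7)$intensities
    volumes <- vector("list", n)
    for (i in seq_len(n)) {
      subj <- array(rnorm(prod(d), sd = 0.5), d)
      subj <- smooth_volume(volume3d(subj), 5)$intensities
      tex <- array(rnorm(prod(d), sd = 0.2), d)
      if (labels[i] == "case") {
        boost <- array(0, d)
        boost[ctr[[1]], ctr[[2]], ctr[[3]]] <-
          rnorm(length(ctr[[1]]) * length(ctr[[2]]) * length(ctr[[3]]),
                sd = 0.2 * contrast)
        tex <- tex + boost
      }
      volumes[[i]] <- volume3d(background + subj + tex)
    }
    split <- rep("holdout", n)
    for (cl in c("case", "control")) {
      idx <- which(labels == cl)
      split[idx[seq_len(round(spec$train_frac * length(idx)))]] <- "train"
    }
    cohort <- validate_cohort(tibble(
      subject_id = sprintf("sub%03d", seq_len(n)), label = labels,
      site = sites, split = split,
      structural_path = "", functional_path = ""))
    list(volumes = volumes, cohort = cohort)
  })
}

#' Write a simulated cohort to disk as NIfTI + TSV
#'
#' Materializes generator output in the same on-disk layout real cohorts
#' use, so the loading path is identical for synthetic and real data.
#'
#' @param fmri Output of [simulate_fmri_cohort()] (or `NULL`).
#' @param structural Output of [simulate_structural_cohort()] (or `NULL`).
#' @param dir Output directory (created if missing).
#' @return Path to the written cohort TSV.
#' @export
write_synthetic_cohort <- function(fmri = NULL, structural = NULL,
                                   dir = tempfile("cohort")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- if (!is.null(fmri)) fmri$cohort else structural$cohort
  tab <- base
  n <- nrow(tab)
  tab$functional_path <- tab$structural_path <- ""
  for (i in seq_len(n)) {
    if (!is.null(fmri)) {
      p <- file.path(dir, paste0(tab$subject_id[i], "_bold.nii.gz"))
      frames <- scatter_to_mask(fmri$series[[i]]$data, fmri$mask)
      write_series(lapply(frames, volume3d), p)
      tab$functional_path[i] <- p
    }
    if (!is.null(structural)) {
      p <- file.path(dir, paste0(tab$subject_id[i], "_anat.nii.gz"))
      write_volume(structural$volumes[[i]], p)
      tab$structural_path[i] <- p
    }
  }
  if (!is.null(fmri)) {
    mp <- file.path(dir, "mask.nii.gz")
    write_volume(volume3d(array(as.numeric(fmri$mask), dim(fmri$mask))), mp)
  }
  path <- file.path(dir, "cohort.tsv")
  write_cohort(tab, path)
  path
}
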