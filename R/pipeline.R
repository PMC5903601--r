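#' Pipeline configuration
#'
#' Bundles the settings for an end-to-end run: which feature path(s) to
#' use, the source-separation backend, component and pooling settings,
#' autoencoder settings and the SVM policy. Per-mode kernel defaults
#' follow the design of pairing non-linear features with a linear
#' classifier and linear features with a non-linear one: the structural
#' (texture) and combined modes use a linear kernel, the functional mode
#' an RBF kernel with an internally cross-validated gamma.
#'
#' @param mode `"combined"`, `"structural"` or `"functional"`.
#' @param backend Separation backend: `"nsd"`, `"pca"`, `"kpca"`, `"ica"`.
#' @param n_components Number of spatial components C.
#' @param var_frac Variance fraction for both PCA levels (default 0.99).
#' @param K_fixed Optional fixed group-PCA row count.
#' @param box_edge Local-covariance region edge for the NSD backend.
#' @param kpca_sigma RBF width for the kernel-PCA backend (`NULL`: median
#'   pairwise-distance heuristic on a column subsample).
#' @param ae_k,ae_rho,ae_beta,ae_lambda,ae_max_iter Autoencoder settings.
#' @param max_patches Patch budget sampled across training volumes.
#' @param patch_edge,pool_edge Texture patch / pooling box edges.
#' @param svm_spec Optional [classifier_spec()] override.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("combined", "structural", "functional"),
                            backend = c("nsd", "pca", "kpca", "ica"),
                            n_components = 4, var_frac = 0.99,
                            K_fixed = NULL, box_edge = 4, kpca_sigma = NULL,
                            ae_k = 3, ae_rho = 0.05, ae_beta = 1,
                            ae_lambda = 1e-4, ae_max_iter = 200,
                            max_patches = 20000, patch_edge = 5,
                            pool_edge = 5, svm_spec = NULL, seed = 1) {
  structure(list(mode = match.arg(mode), backend = match.arg(backend),
                 n_components = n_components, var_frac = var_frac,
                 K_fixed = K_fixed, box_edge = box_edge,
                 kpca_sigma = kpca_sigma, ae_k = ae_k, ae_rho = ae_rho,
                 ae_beta = ae_beta, ae_lambda = ae_lambda,
                 ae_max_iter = ae_max_iter, max_patches = max_patches,
                 patch_edge = patch_edge, pool_edge = pool_edge,
                 svm_spec = svm_spec, seed = seed),
            class = "pipeline_config")
}

default_svm_spec <- function(mode) {
  switch(mode,
         structural = classifier_spec("linear", standardize = FALSE),
         functional = classifier_spec("rbf", standardize = TRUE),
         combined = classifier_spec("linear", standardize = TRUE))
}

extract_structural_features <- function(volumes, train_idx, config) {
  squashed <- lapply(volumes, texture_normalize)
  pools <- lapply(squashed[train_idx], function(v)
    extract_patches(v, edge = config$patch_edge,
                    max_patches = ceiling(config$max_patches /
                                            length(train_idx)),
                    seed = config$seed)$patches)
  D <- do.call(rbind, pools)
  fit <- train_autoencoder(D, k = config$ae_k, rho = config$ae_rho,
                           beta = config$ae_beta, lambda = config$ae_lambda,
                           seed = config$seed, max_iter = config$ae_max_iter)
  feats <- t(vapply(squashed, function(v)
    structural_feature_vector(v, fit$bank, config$pool_edge)$vector,
    numeric(fit$bank$k *
              prod(pool_grid_dims(dim(as_volume_array(volumes[[1]])) -
                                    config$patch_edge + 1L,
                                  config$pool_edge)))))
  list(features = feats, bank = fit$bank, ae_fit = fit)
}

extract_functional_features <- function(series, mask, train_idx, config) {
  t_common <- min(vapply(series, function(b) nrow(b$data), integer(1)))
  data <- lapply(series, function(b) b$data[seq_len(t_common), , drop = FALSE])
  subj <- lapply(data, subject_pca, var_frac = config$var_frac)
  gp <- group_pca(lapply(subj[train_idx], `[[`, "Y"),
                  var_frac = config$var_frac, K_fixed = config$K_fixed,
                  C_min = config$n_components)
  X <- gp$X
  C <- config$n_components
  sep <- switch(config$backend,
    pca = separate_pca(X, C),
    kpca = {
      sigma <- config$kpca_sigma
      if (is.null(sigma)) {
        cols <- unclass(X)[, with_seed(config$seed,
          sample.int(ncol(X), min(300, ncol(X)))), drop = FALSE]
        sigma <- median(dist(t(cols)))
      }
      separate_kpca(X, sigma, C)
    },
    ica = separate_ica(X, C, seed = config$seed),
    nsd = {
      field <- local_covariances(X, mask, box_edge = config$box_edge)
      model <- fit_nsd(field, C, seed = config$seed)
      maps <- extract_nsd_sources(X, model, force = TRUE)
      list(maps = maps, mixing = mixing_estimate(model$A), model = model)
    })
  S <- sep$maps$S
  n <- length(series)
  feats <- matrix(NA_real_, n, t_common * C)
  for (i in seq_len(n)) {
    Ai <- if (i %in% train_idx) {
      back_reconstruct(subj[[i]]$reduction, gp$reduction,
                       match(i, train_idx), sep$mixing$A)
    } else {
      project_timecourses(data[[i]], S)
    }
    feats[i, ] <- fmri_feature_vector(Ai)
  }
  list(features = feats, maps = sep$maps, mixing = sep$mixing,
       model = sep$model, t_common = t_common)
}

#' Run the full classification pipeline
#'
#' Executes the configured feature path(s) on a cohort, fitting every
#' learned stage (texture filters, reductions, spatial maps, feature
#' scalers, SVM hyperparameters) on the training split only; holdout
#' subjects pass through the fitted transforms (filter bank applied as-is;
#' time courses obtained by projecting onto the training-set spatial
#' maps) and are touched exactly once, at final evaluation. Returns the
#' holdout evaluation, the training cross-validated accuracy, the fitted
#' model and a reproducibility manifest.
#'
#' @param cohort Cohort tibble (see [validate_cohort()]); `split` decides
#'   train vs holdout.
#' @param functional Ordered list of [bold_series()] matching the cohort
#'   rows (required unless mode is `"structural"`); if `NULL`, loaded from
#'   `cohort$functional_path` using `mask`.
#' @param structural Ordered list of [volume3d()] (required unless mode is
#'   `"functional"`); if `NULL`, loaded from `cohort$structural_path`.
#' @param mask Logical 3D array; required when loading functional data
#'   from disk and for the NSD backend.
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result` with `report` (holdout
#'   [evaluate_predictions()]), `cv_accuracy`, `model`, `features`,
#'   `maps`, `bank`, `predictions` tibble and `manifest`.
#' @export
run_pipeline <- function(cohort, functional = NULL, structural = NULL,
                         mask = NULL, config = pipeline_config()) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  train_idx <- which(cohort$split == "train")
  hold_idx <- which(cohort$split == "holdout")
  if (length(train_idx) < 4 || length(hold_idx) < 1)
    abort("need a train split (>= 4 subjects) and a non-empty holdout split")
  need_f <- config$mode %in% c("functional", "combined")
  need_s <- config$mode %in% c("structural", "combined")
  if (need_f && is.null(functional)) {
    if (is.null(mask)) abort("`mask` is required to load functional data")
    functional <- lapply(seq_len(n), function(i)
      vectorize_series(read_series(cohort$functional_path[i]), mask,
                       subject_id = cohort$subject_id[i],
                       site = cohort$site[i], label = cohort$label[i]))
  }
  if (need_s && is.null(structural))
    structural <- lapply(cohort$structural_path, read_volume)
  if (need_f && is.null(mask)) mask <- functional[[1]]$mask

  sf <- if (need_s) extract_structural_features(structural, train_idx, config)
  ff <- if (need_f) extract_functional_features(functional, mask, train_idx,
                                                config)
  features <- switch(config$mode,
                     structural = sf$features,
                     functional = ff$features,
                     combined = combine_features(sf$features, ff$features))
  spec <- if (is.null(config$svm_spec)) default_svm_spec(config$mode)
          else config$svm_spec
  y <- as_label_factor(cohort$label)
  cv <- cv_accuracy(features[train_idx, , drop = FALSE], y[train_idx],
                    spec, seed = config$seed)
  model <- train_svm(features[train_idx, , drop = FALSE], y[train_idx],
                     spec, seed = config$seed)
  pred_hold <- predict(model, features[hold_idx, , drop = FALSE])
  report <- evaluate_predictions(pred_hold, y[hold_idx])
  predictions <- tibble(subject_id = cohort$subject_id[hold_idx],
                        truth = as.character(y[hold_idx]),
                        pred = as.character(pred_hold),
                        split = "holdout")
  manifest <- list(
    mode = config$mode, backend = config$backend, seed = config$seed,
    config_hash = rlang::hash(config), n_train = length(train_idx),
    n_holdout = length(hold_idx),
    holdout_access = "holdout subjects only transformed by fitted stages; labels used once, at final evaluation")
  structure(list(report = report, cv_accuracy = cv$accuracy, model = model,
                 features = features, maps = if (need_f) ff$maps,
                 nsd_model = if (need_f) ff$model,
                 bank = if (need_s) sf$bank,
                 predictions = predictions, config = config,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> mode ", x$config$mode, " (backend ",
      x$config$backend, "): train CV accuracy ", round(x$cv_accuracy, 4),
      ", holdout accuracy ", round(x$report$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(tibble(mode = x$config$mode, backend = x$config$backend,
                          cv_accuracy = x$cv_accuracy),
                   glance(x$report))
}

#' Write holdout predictions as TSV
#'
#' @param x A `pipeline_result`.
#' @param path Output path.
#' @export
write_predictions <- function(x, path) {
  readr::write_tsv(x$predictions, path)
  invisible(path)
}
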