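# Functional-path features for a whole simulated cohort (no holdout):
# subject PCA -> group PCA -> chosen backend -> back-reconstruction.
functional_features_all <- function(sim, C = 4, backend = "nsd",
                                    var_frac = 0.99, seed = 1) {
  data <- lapply(sim$series, `[[`, "data")
  subj <- lapply(data, subject_pca, var_frac = var_frac)
  gp <- group_pca(lapply(subj, `[[`, "Y"), var_frac = var_frac, C_min = C)
  X <- gp$X
  sep <- if (backend == "nsd") {
    field <- local_covariances(X, sim$mask, box_edge = 4)
    model <- fit_nsd(field, C, seed = seed)
    list(maps = extract_nsd_sources(X, model, force = TRUE),
         mixing = mixing_estimate(model$A))
  } else if (backend == "ica") {
    separate_ica(X, C, seed = seed)
  } else {
    separate_pca(X, C)
  }
  feats <- t(vapply(seq_along(data), function(i)
    fmri_feature_vector(back_reconstruct(subj[[i]]$reduction, gp$reduction,
                                         i, sep$mixing$A)),
    numeric(nrow(data[[1]]) * C)))
  list(features = feats, maps = sep$maps, mixing = sep$mixing,
       labels = sim$cohort$label, sites = sim$cohort$site)
}
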