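test_that("source generation is a pure function of the spec seed", {
  spec <- synthetic_spec(dims = c(12, 12, 8), C_true = 3, seed = 11)
  a <- simulate_nonstationary_sources(spec)
  b <- simulate_nonstationary_sources(spec)
  expect_identical(a$S_true, b$S_true)
  sim_a <- simulate_fmri_cohort(spec, a$S_true)
  sim_b <- simulate_fmri_cohort(spec, b$S_true)
  expect_identical(sim_a$series[[3]]$data, sim_b$series[[3]]$data)
  st_a <- simulate_structural_cohort(spec)
  st_b <- simulate_structural_cohort(spec)
  expect_identical(st_a$volumes[[2]]$intensities,
                   st_b$volumes[[2]]$intensities)
})

test_that("scale fields reproduce the Laplacian variance law", {
  spec <- synthetic_spec(dims = c(20, 20, 12), C_true = 1, seed = 12,
                         lambda_active = 0.5, lambda_background = 0.5)
  src <- simulate_nonstationary_sources(spec)
  # constant rate 0.5 over 4800 voxels: var = 2 / lambda^2 = 8 within 10%
  expect_lt(abs(var(src$S_true[1, ]) / 8 - 1), 0.1)

  spec2 <- synthetic_spec(dims = c(24, 24, 16), C_true = 2, seed = 13)
  src2 <- simulate_nonstationary_sources(spec2)
  active <- src2$lambda_fields[1, ] == spec2$lambda_active
  expect_lt(abs(var(src2$S_true[1, active]) /
                  (2 / spec2$lambda_active^2) - 1), 0.1)
  # disjoint high-variance regions -> components nearly uncorrelated
  expect_lt(abs(cor(src2$S_true[1, ], src2$S_true[2, ])), 0.05)
})

test_that("noiseless zero-effect cohorts satisfy the exact model", {
  spec <- synthetic_spec(n_subjects = 4, dims = c(8, 8, 4), t_len = 10,
                         C_true = 2, effect_size = 0, site_offset = 0,
                         noise_sd = 0, seed = 14)
  src <- simulate_nonstationary_sources(spec)
  sim <- simulate_fmri_cohort(spec, src$S_true)
  for (i in 1:4)
    expect_equal(sim$series[[i]]$data, sim$A_true[[i]] %*% src$S_true,
                 tolerance = 1e-12)
  expect_true(all(vapply(sim$series, function(b)
    all(is.finite(b$data)) && nrow(b$data) == 10, logical(1))))
})

test_that("the reduction+NSD pipeline recovers planted time courses", {
  spec <- synthetic_spec(n_subjects = 20, dims = c(20, 20, 12), t_len = 40,
                         C_true = 4, effect_size = 0, site_offset = 0,
                         noise_sd = 0.1, seed = 15)
  src <- simulate_nonstationary_sources(spec)
  sim <- simulate_fmri_cohort(spec, src$S_true)
  out <- functional_features_all(sim, C = 4, backend = "nsd",
                                 var_frac = 0.999)
  al <- align_components(out$maps$S, src$S_true)
  data <- lapply(sim$series, `[[`, "data")
  cors <- vapply(seq_along(data), function(i) {
    Ai <- matrix(out$features[i, ], spec$t_len, 4)
    Ai_aligned <- Ai[, al$permutation] * rep(al$signs, each = spec$t_len)
    median(abs(diag(cor(Ai_aligned, sim$A_true[[i]]))))
  }, numeric(1))
  expect_gte(median(cors), 0.9)
})

test_that("dominant site offsets plant a detectable confound", {
  spec <- synthetic_spec(n_subjects = 40, dims = c(12, 12, 8), t_len = 30,
                         C_true = 3, effect_size = 0, n_sites = 2,
                         site_offset = 3, noise_sd = 0.1, seed = 16)
  src <- simulate_nonstationary_sources(spec)
  sim <- simulate_fmri_cohort(spec, src$S_true)
  out <- functional_features_all(sim, C = 3, backend = "pca")
  site_as_label <- ifelse(sim$cohort$site == "site1", "case", "control")
  cv <- cv_accuracy(out$features, site_as_label,
                    classifier_spec("linear"), seed = 2)
  expect_gte(cv$accuracy, 0.9)
})

test_that("structural texture contrast drives texture-path separability", {
  spec0 <- synthetic_spec(n_subjects = 40, dims = c(24, 24, 24), seed = 17)
  run_texture_cv <- function(contrast) {
    st <- simulate_structural_cohort(spec0, contrast = contrast)
    vols <- lapply(st$volumes, texture_normalize)
    D <- do.call(rbind, lapply(vols[seq(1, 40, by = 4)], function(v)
      extract_patches(v, max_patches = 400, seed = 18)$patches))
    fit <- train_autoencoder(D, k = 3, seed = 19, max_iter = 150)
    feats <- t(vapply(vols, function(v)
      structural_feature_vector(v, fit$bank)$vector,
      numeric(3 * prod(pool_grid_dims(c(20, 20, 20), 5)))))
    cv_accuracy(feats, st$cohort$label,
                classifier_spec("linear", standardize = FALSE),
                seed = 20)$accuracy
  }
  acc_strong <- run_texture_cv(2)
  expect_gte(acc_strong, 0.85)
  acc_null <- run_texture_cv(0)
  expect_lt(abs(acc_null - 0.5), 2 * sqrt(0.25 / 40))
})

test_that("synthetic cohorts round-trip through NIfTI + TSV", {
  spec <- synthetic_spec(n_subjects = 3, dims = c(6, 6, 4), t_len = 5,
                         C_true = 2, seed = 21)
  src <- simulate_nonstationary_sources(spec)
  sim <- simulate_fmri_cohort(spec, src$S_true)
  st <- simulate_structural_cohort(spec)
  dir <- withr::local_tempdir()
  path <- write_synthetic_cohort(sim, st, dir = dir)
  tab <- load_cohort(path)
  expect_equal(nrow(tab), 3L)
  mask <- read_volume(file.path(dir, "mask.nii.gz"))$intensities != 0
  frames <- read_series(tab$functional_path[1])
  b <- vectorize_series(frames, mask, 5, subject_id = tab$subject_id[1])
  expect_equal(b$data, sim$series[[1]]$data, tolerance = 1e-5,
               ignore_attr = TRUE)
  v <- read_volume(tab$structural_path[2])
  expect_equal(v$intensities, st$volumes[[2]]$intensities, tolerance = 1e-5)
})
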