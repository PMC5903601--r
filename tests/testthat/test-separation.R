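test_that("identity backend slices the representative matrix", {
  set.seed(51)
  X <- matrix(rnorm(5 * 80), 5, 80)
  out <- separate_pca(X, C = 5)
  expect_equal(out$maps$S, X)
  expect_equal(crossprod(out$mixing$A), diag(5))
  out3 <- separate_pca(X, C = 3)
  expect_equal(out3$maps$S, X[1:3, ])
  expect_error(separate_pca(X, C = 6), "<= K")
})

test_that("identity-backend back-reconstruction equals direct slicing", {
  cohort <- exact_model_cohort(n = 3, Tn = 10, C = 3, V = 300, seed = 59)
  subj <- lapply(cohort$data, subject_pca, var_frac = 0.999999)
  gp <- group_pca(lapply(subj, `[[`, "Y"), var_frac = 0.999999)
  C <- 2
  sep <- separate_pca(gp$X, C)
  Fdag <- MASS::ginv(gp$reduction$F)
  for (i in 1:3) {
    Ai <- back_reconstruct(subj[[i]]$reduction, gp$reduction, i, sep$mixing$A)
    direct <- (t(subj[[i]]$reduction$U) %*%
                 Fdag[gp$reduction$blocks[[i]], , drop = FALSE])[, seq_len(C)]
    expect_equal(unclass(Ai), direct, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("kernel PCA produces a PSD centered kernel and valid maps", {
  set.seed(52)
  X <- matrix(rnorm(4 * 60), 4, 60)
  out <- separate_kpca(X, sigma = 2, C = 3)
  expect_true(all(out$eigenvalues > -1e-8 * max(abs(out$eigenvalues))))
  expect_equal(dim(out$maps$S), c(3L, 60L))
  expect_equal(dim(out$mixing$A), c(4L, 3L))
  # sigma -> infinity: kernel constant, centered kernel ~ 0, maps ~ 0
  far <- separate_kpca(X, sigma = 1e6 * sd(X), C = 2)
  expect_lt(max(abs(far$maps$S)), 1e-3)
  expect_error(separate_kpca(X, sigma = 0, C = 2), "sigma")
  expect_error(separate_kpca(matrix(0, 2, 6000), 1, 2), "guard")
})

test_that("ICA log-likelihood is non-decreasing over accepted steps", {
  set.seed(53)
  S <- matrix(rexp(2 * 3000) * sample(c(-1, 1), 6000, TRUE), 2, 3000)
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  res <- separate_ica(A %*% S, 2, seed = 1)
  expect_true(all(diff(res$loglik_trace) >= -1e-9))
})

test_that("ICA separates seeded Laplacian mixtures accurately", {
  set.seed(54)
  for (C in c(2, 4)) {
    V <- 8000
    S <- matrix(rexp(C * V) * sample(c(-1, 1), C * V, TRUE), C, V) / sqrt(2)
    A <- matrix(rnorm(C * C), C, C) + 2 * diag(C)   # well-conditioned
    res <- separate_ica(A %*% S, C, seed = 7)
    expect_lt(amari_index(res$unmixing %*% A), 0.05)
  }
})

test_that("ICA on already-independent rows returns ~identity mixing", {
  set.seed(55)
  C <- 3; V <- 10000
  X <- matrix(rexp(C * V) * sample(c(-1, 1), C * V, TRUE), C, V)
  res <- separate_ica(X, C, seed = 2)
  al <- align_components(res$maps$S, X)
  expect_true(all(al$correlations >= 0.99))
})

test_that("ICA is deterministic given a seed", {
  set.seed(56)
  X <- matrix(rnorm(3 * 2000), 3, 2000)^3      # non-Gaussian rows
  a <- separate_ica(X, 3, seed = 9)
  b <- separate_ica(X, 3, seed = 9)
  expect_identical(a$maps$S, b$maps$S)
})

test_that("all backends satisfy X ~ A S at C = K on noiseless data", {
  set.seed(57)
  K <- 4; V <- 500
  X <- matrix(rexp(K * V) * sample(c(-1, 1), K * V, TRUE), K, V)
  for (backend in c("pca", "ica")) {
    out <- switch(backend, pca = separate_pca(X, K),
                  ica = separate_ica(X, K, seed = 3))
    rec <- out$mixing$A %*% out$maps$S
    expect_lt(norm(rec - X, "F") / norm(X, "F"), 1e-6)
  }
})

test_that("component alignment recovers permutations and signs", {
  set.seed(58)
  S <- matrix(rnorm(4 * 300), 4, 300)
  al <- align_components(S, S)
  expect_equal(al$permutation, 1:4)
  expect_true(all(al$correlations > 1 - 1e-12))
  expect_lt(al$amari_index, 1e-8)

  perm <- c(3, 1, 4, 2); signs <- c(-1, 1, -1, 1)
  S_est <- S[perm, ] * signs
  al2 <- align_components(S_est, S)
  # est row al2$permutation[i] matches true row i
  expect_equal(al2$permutation, order(perm))
  expect_equal(al2$signs, signs[order(perm)])

  rnd <- align_components(matrix(rnorm(4 * 5000), 4, 5000),
                          matrix(rnorm(4 * 5000), 4, 5000))
  expect_gte(rnd$amari_index, 0.2)
  expect_error(align_components(matrix(0, 2, 10), matrix(rnorm(20), 2, 10)),
               "zero-variance")
})
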