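test_that("subject PCA captures exact low rank and reconstructs", {
  set.seed(31)
  B <- matrix(rnorm(2 * 50), 2, 50)
  W <- matrix(rnorm(8 * 2), 8, 2)
  data <- W %*% B
  data <- data - rowMeans(data)          # keep centering a no-op
  out <- subject_pca(data, var_frac = 0.99)
  expect_equal(out$reduction$T_red, 2L)
  rec <- t(out$reduction$U) %*% out$Y
  expect_lt(norm(rec - data, "F") / norm(data, "F"), 1e-8)
  expect_gte(out$reduction$var_captured, 0.99)
  # rows of U orthonormal
  expect_lt(max(abs(tcrossprod(out$reduction$U) - diag(2))), 1e-8)
})

test_that("subject PCA eigenvalues match a dense eigendecomposition", {
  set.seed(32)
  data <- matrix(rnorm(6 * 40), 6, 40)
  out <- subject_pca(data, var_frac = 0.999)
  Xc <- data - rowMeans(data)
  want <- eigen(tcrossprod(Xc), symmetric = TRUE)$values
  expect_equal(out$reduction$eigenvalues, pmax(want, 0), tolerance = 1e-8)
  # energy conservation: retained + discarded = total
  expect_lt(abs(sum(out$reduction$eigenvalues) - sum(Xc^2)), 1e-8 * sum(Xc^2))
})

test_that("group PCA of identical subjects recovers the shared row space", {
  set.seed(33)
  Y <- matrix(rnorm(3 * 60), 3, 60)
  Y <- Y - rowMeans(Y)
  gp <- group_pca(list(Y, Y, Y, Y), var_frac = 0.99)
  expect_equal(nrow(gp$X), gp$reduction$K)
  expect_equal(ncol(gp$X), 60L)
  expect_gte(gp$reduction$var_captured, 0.99)
  # principal angles between row spaces ~ 0
  Q1 <- qr.Q(qr(t(Y)))
  Q2 <- qr.Q(qr(t(unclass(gp$X))))
  angles <- acos(pmin(svd(crossprod(Q1, Q2))$d, 1))
  expect_lt(max(angles), 1e-6)
})

test_that("group PCA commutes with voxel permutation", {
  set.seed(34)
  Ys <- lapply(1:3, function(i) matrix(rnorm(4 * 30), 4, 30))
  perm <- sample(30)
  a <- group_pca(Ys, var_frac = 0.999)
  b <- group_pca(lapply(Ys, function(Y) Y[, perm]), var_frac = 0.999)
  expect_equal(abs(unclass(b$X)), abs(unclass(a$X)[, perm, drop = FALSE]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(group_pca(list(Ys[[1]], Ys[[2]][, 1:10])), "voxel")
})

test_that("back-reconstruction is the identity for identity reductions", {
  A <- matrix(rnorm(12), 4, 3)
  sr <- structure(list(U = diag(4), eigenvalues = rep(1, 4), T_red = 4L,
                       var_captured = 1, row_center = rep(0, 4)),
                  class = "subject_reduction")
  gr <- structure(list(F = diag(4), blocks = list(1:4), K = 4L,
                       var_captured = 1, row_center = rep(0, 4)),
                  class = "group_reduction")
  Ai <- back_reconstruct(sr, gr, 1, A)
  expect_equal(unclass(Ai), A, ignore_attr = TRUE)
})

test_that("noiseless round trip through both PCA levels is exact", {
  cohort <- exact_model_cohort(n = 5, Tn = 12, C = 3, V = 400, seed = 41)
  subj <- lapply(cohort$data, subject_pca, var_frac = 0.999999)
  gp <- group_pca(lapply(subj, `[[`, "Y"), var_frac = 0.999999)
  sep <- separate_pca(gp$X, C = gp$reduction$K)
  for (i in seq_along(cohort$data)) {
    Ai <- back_reconstruct(subj[[i]]$reduction, gp$reduction, i,
                           sep$mixing$A)
    expect_equal(dim(unclass(Ai)), c(12L, gp$reduction$K))
    err <- norm(unclass(Ai) %*% sep$maps$S - cohort$data[[i]], "F") /
      norm(cohort$data[[i]], "F")
    expect_lt(err, 1e-6)
  }
})

test_that("feature flattening is component-major and invertible", {
  tc <- matrix(1:6, 3, 2)
  f <- fmri_feature_vector(tc)
  expect_length(f, 6L)
  expect_equal(f, as.numeric(tc))
  expect_equal(matrix(f, 3, 2), tc)
  expect_identical(fmri_feature_vector(tc), fmri_feature_vector(tc + 0))
})

test_that("projection onto maps recovers noiseless time courses", {
  cohort <- exact_model_cohort(n = 2, Tn = 10, C = 3, V = 300, seed = 42)
  Ai <- project_timecourses(cohort$data[[1]], cohort$S)
  expect_equal(unclass(Ai), cohort$A_true[[1]], tolerance = 1e-8,
               ignore_attr = TRUE)
})
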