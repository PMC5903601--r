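test_that("patch extraction enumerates every corner position", {
  v5 <- random_volume(c(5, 5, 5), seed = 1)
  pm <- extract_patches(v5, edge = 5)
  expect_equal(nrow(pm$patches), 1L)
  expect_equal(as.numeric(pm$patches[1, ]), as.numeric(v5$intensities))

  v <- random_volume(c(7, 6, 5), seed = 2)
  pm <- extract_patches(v, edge = 5)
  expect_equal(nrow(pm$patches), 3L * 2L * 1L)
  # brute-force enumeration oracle on a couple of rows
  for (r in c(1, 4, 6)) {
    cc <- pm$positions[r, ]
    cube <- v$intensities[cc[1]:(cc[1] + 4), cc[2]:(cc[2] + 4),
                          cc[3]:(cc[3] + 4)]
    expect_equal(as.numeric(pm$patches[r, ]), as.numeric(cube))
  }
  expect_error(extract_patches(random_volume(c(4, 8, 8)), edge = 5),
               "smaller")
})

test_that("full-scale patch counts match the per-axis product", {
  g <- patch_grid_dims(c(79, 95, 68), edge = 5)
  expect_equal(g, c(75L, 91L, 64L))
  expect_equal(prod(g), 436800)
  # cross-check the formula by enumeration on a shrunken grid
  v <- random_volume(c(9, 8, 7), seed = 3)
  expect_equal(nrow(extract_patches(v)$patches),
               prod(patch_grid_dims(c(9, 8, 7))))
})

test_that("seeded patch subsampling caps rows reproducibly", {
  v <- random_volume(c(8, 8, 8), seed = 4)
  a <- extract_patches(v, max_patches = 10, seed = 7)
  b <- extract_patches(v, max_patches = 10, seed = 7)
  expect_equal(nrow(a$patches), 10L)
  expect_identical(a$patches, b$patches)
})

test_that("KL sparsity term vanishes at the target activation", {
  expect_equal(brainsep:::kl_bernoulli(0.05, 0.05), 0)
  expect_gt(brainsep:::kl_bernoulli(0.05, 0.5), 0)
})

test_that("all-zero parameters give the closed-form objective", {
  set.seed(6)
  n <- 8; k <- 2; m <- 5
  D <- matrix(runif(m * n), m, n)
  p <- ae_params(matrix(0, k, n), rep(0, k), matrix(0, n, k), rep(0, n),
                 rho = 0.05, beta = 0.7, lambda = 0.1)
  got <- ae_objective(p, D)$objective
  want <- sum((D - 0.5)^2) / (2 * m) +
    0.7 * k * brainsep:::kl_bernoulli(0.05, 0.5)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("analytic autoencoder gradient matches central finite differences", {
  set.seed(11)
  for (case in 1:8) {
    n <- sample(4:10, 1); k <- sample(1:3, 1); m <- sample(3:7, 1)
    D <- matrix(runif(m * n), m, n)
    p <- random_ae_params(n, k, seed = 100 + case)
    got <- ae_objective(p, D)$gradient
    fd <- ae_fd_gradient(p, D)
    expect_lt(max(abs(got - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("autoencoder training reduces the objective and yields filters", {
  set.seed(12)
  D <- extract_patches(texture_normalize(random_volume(c(9, 9, 9), seed = 13)),
                       edge = 5, max_patches = 60)$patches
  fit <- train_autoencoder(D, k = 3, seed = 2, max_iter = 150)
  expect_lte(fit$objective, fit$initial_objective)
  expect_equal(fit$bank$k, 3L)
  expect_length(fit$bank$filters, 3L)
  expect_equal(dim(fit$bank$filters[[1]]), c(5L, 5L, 5L))
  expect_length(fit$bank$filters[[1]], 125L)
})

test_that("identical rows are reconstructed almost exactly without penalties", {
  row <- sigmoid(rnorm(12))
  D <- matrix(row, 20, 12, byrow = TRUE)
  fit <- train_autoencoder(D, k = 2, beta = 0, lambda = 0, seed = 3,
                           max_iter = 400, pgtol = 1e-9)
  p <- fit$params
  H <- sigmoid(D %*% t(p$theta1) + matrix(p$b1, 20, 2, byrow = TRUE))
  Xhat <- sigmoid(H %*% t(p$theta2) + matrix(p$b2, 20, 12, byrow = TRUE))
  expect_lt(sum((D - Xhat)^2) / (2 * nrow(D)), 1e-4)
})

test_that("filter banks survive a TSV round trip", {
  dir <- withr::local_tempdir()
  set.seed(14)
  bank <- filter_bank(matrix(rnorm(3 * 125), 3, 125), rnorm(3), edge = 5)
  p <- file.path(dir, "bank.tsv")
  write_filter_bank(bank, p)
  back <- read_filter_bank(p)
  expect_equal(back$biases, bank$biases, tolerance = 1e-12)
  expect_equal(back$filters[[2]], bank$filters[[2]], tolerance = 1e-12)
})
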