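#' Sparse autoencoder parameter set
#'
#' Bundles encoding/decoding weights, biases and the regularization
#' hyperparameters of a single-hidden-layer sparse autoencoder with
#' sigmoid activations.
#'
#' @param theta1 k x n encoding weights.
#' @param b1 Length-k encoding biases.
#' @param theta2 n x k decoding weights.
#' @param b2 Length-n decoding biases.
#' @param rho Sparsity target in (0, 1), the desired mean activation of
#'   each hidden unit (default 0.05).
#' @param beta Weight of the KL sparsity penalty.
#' @param lambda Weight-decay coefficient on `theta1`/`theta2`.
#' @return An object of class `ae_params`.
#' @export
ae_params <- function(theta1, b1, theta2, b2, rho = 0.05, beta = 1,
                      lambda = 1e-4) {
  k <- nrow(theta1); n <- ncol(theta1)
  if (!identical(dim(theta2), c(n, k)))
    abort("`theta2` must be n x k, the transpose shape of `theta1`")
  if (length(b1) != k || length(b2) != n) abort("bias lengths inconsistent")
  if (rho <= 0 || rho >= 1) abort("`rho` must lie in (0, 1)")
  structure(list(theta1 = theta1, b1 = as.numeric(b1), theta2 = theta2,
                 b2 = as.numeric(b2), rho = rho, beta = beta,
                 lambda = lambda, k = k, n = n),
            class = "ae_params")
}

ae_flatten <- function(p) {
  c(as.numeric(p$theta1), p$b1, as.numeric(p$theta2), p$b2)
}

ae_unflatten <- function(vec, k, n, rho, beta, lambda) {
  i <- 0L
  theta1 <- matrix(vec[i + seq_len(k * n)], k, n); i <- i + k * n
  b1 <- vec[i + seq_len(k)]; i <- i + k
  theta2 <- matrix(vec[i + seq_len(n * k)], n, k); i <- i + n * k
  b2 <- vec[i + seq_len(n)]
  ae_params(theta1, b1, theta2, b2, rho, beta, lambda)
}

# Bernoulli KL divergence KL(rho || rho_hat), vectorized over rho_hat.
kl_bernoulli <- function(rho, rho_hat) {
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse autoencoder objective and analytic gradient
#'
#' Evaluates
#' `J = (1 / (2 m)) * sum_x ||x - xhat||^2 + beta * sum_j KL(rho || rhohat_j)
#'  + lambda * (||theta1||^2 + ||theta2||^2)`
#' where `h = sigmoid(theta1 x + b1)`, `xhat = sigmoid(theta2 h + b2)` and
#' `rhohat_j` is the mean activation of hidden unit j over the data, along
#' with the exact gradient with respect to all parameters (flattened in the
#' order theta1, b1, theta2, b2). Mean activations are clamped to
#' `[1e-8, 1 - 1e-8]` so the KL term stays finite.
#'
#' @param params An [ae_params()].
#' @param D An m x n data matrix or a `patch_matrix`.
#' @return List with `objective` (scalar) and `gradient` (flat vector).
#' @export
ae_objective <- function(params, D) {
  if (inherits(D, "patch_matrix")) D <- D$patches
  if (!is.matrix(D) || nrow(D) < 1L) abort("`D` must have at least one row")
  if (ncol(D) != params$n) abort("data dimension does not match `theta1`")
  m <- nrow(D)
  eps <- 1e-8
  H <- sigmoid(D %*% t(params$theta1) +
                 matrix(params$b1, m, params$k, byrow = TRUE))
  Xhat <- sigmoid(H %*% t(params$theta2) +
                    matrix(params$b2, m, params$n, byrow = TRUE))
  rho_hat <- pmin(pmax(colMeans(H), eps), 1 - eps)
  obj <- sum((D - Xhat)^2) / (2 * m) +
    params$beta * sum(kl_bernoulli(params$rho, rho_hat)) +
    params$lambda * (sum(params$theta1^2) + sum(params$theta2^2))

  delta3 <- -(D - Xhat) * Xhat * (1 - Xhat) / m          # m x n
  g_theta2 <- t(delta3) %*% H + 2 * params$lambda * params$theta2
  g_b2 <- colSums(delta3)
  dkl <- -params$rho / rho_hat + (1 - params$rho) / (1 - rho_hat)
  delta2 <- (delta3 %*% params$theta2 +
               matrix(params$beta * dkl / m, m, params$k, byrow = TRUE)) *
    H * (1 - H)                                          # m x k
  g_theta1 <- t(delta2) %*% D + 2 * params$lambda * params$theta1
  g_b1 <- colSums(delta2)
  list(objective = obj,
       gradient = c(as.numeric(g_theta1), g_b1, as.numeric(g_theta2), g_b2))
}

#' Texture filter bank
#'
#' `k` cubic filters plus biases, derived from the encoding weights of a
#' trained sparse autoencoder: row j of `theta1` reshaped to an
#' `edge`^3 cube, with bias `b1[j]`.
#'
#' @param theta1 k x edge^3 encoding weight matrix.
#' @param b1 Length-k biases.
#' @param edge Filter edge length.
#' @return Object of class `filter_bank` with `filters` (list of 3D
#'   arrays) and `biases`.
#' @export
filter_bank <- function(theta1, b1, edge = 5) {
  if (ncol(theta1) != edge^3) abort("`theta1` columns must equal edge^3")
  filters <- lapply(seq_len(nrow(theta1)), function(j)
    array(theta1[j, ], dim = rep(edge, 3)))
  structure(list(filters = filters, biases = as.numeric(b1), edge = edge,
                 k = nrow(theta1)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", x$k, " filters of ", x$edge, "^3 weights\n", sep = "")
  invisible(x)
}

#' Train a sparse autoencoder on patches and extract texture filters
#'
#' Minimizes [ae_objective()] with L-BFGS-B from a seeded small uniform
#' initialization (weights in +/- sqrt(6 / (n + k)), biases zero), then
#' returns both the fitted parameters and the [filter_bank()] built from
#' the encoding weights.
#'
#' @param D m x n patch matrix (or `patch_matrix`), m >= k.
#' @param k Hidden size / number of filters (default 3).
#' @param rho Sparsity target (default 0.05).
#' @param beta Sparsity penalty weight (default 1).
#' @param lambda Weight decay (default 1e-4).
#' @param seed RNG seed for the initialization.
#' @param max_iter L-BFGS iteration cap (default 400).
#' @param pgtol Projected-gradient infinity-norm stopping tolerance.
#' @return List of class `ae_fit` with `params`, `bank`, `objective`,
#'   `initial_objective`, `convergence`.
#' @export
train_autoencoder <- function(D, k = 3, rho = 0.05, beta = 1, lambda = 1e-4,
                              seed = 1, max_iter = 400, pgtol = 1e-5) {
  if (inherits(D, "patch_matrix")) D <- D$patches
  if (nrow(D) < k) abort("need at least `k` patches")
  n <- ncol(D)
  r <- sqrt(6 / (n + k))
  init <- with_seed(seed, c(runif(k * n, -r, r), rep(0, k),
                            runif(n * k, -r, r), rep(0, n)))
  fn <- function(par) {
    o <- ae_objective(ae_unflatten(par, k, n, rho, beta, lambda), D)$objective
    if (!is.finite(o)) abort("non-finite autoencoder objective")
    o
  }
  gr <- function(par)
    ae_objective(ae_unflatten(par, k, n, rho, beta, lambda), D)$gradient
  fit <- optim(init, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = pgtol))
  params <- ae_unflatten(fit$par, k, n, rho, beta, lambda)
  edge <- round(n^(1 / 3))
  bank <- if (edge^3 == n) filter_bank(params$theta1, params$b1, edge) else NULL
  structure(list(params = params, bank = bank, objective = fit$value,
                 initial_objective = fn(init), convergence = fit$convergence),
            class = "ae_fit")
}

#' Select autoencoder hyperparameters by internal cross-validation
#'
#' Grid search over (beta, lambda, rho) scored by held-out reconstruction
#' error under seeded 5-fold splits of the patch rows.
#'
#' @param D Patch matrix.
#' @param k Hidden size.
#' @param grid Data frame with columns `beta`, `lambda`, `rho`; defaults to
#'   beta in {0.1, 1, 3}, lambda in {1e-4, 1e-3}, rho in {0.01, 0.05}.
#' @param folds Number of CV folds (default 5).
#' @param seed RNG seed.
#' @param max_iter Training iteration cap per fit (kept small for CV).
#' @return List with `best` (row of the grid) and `scores` tibble.
#' @export
select_ae_hyperparams <- function(D, k = 3, grid = NULL, folds = 5, seed = 1,
                                  max_iter = 100) {
  if (inherits(D, "patch_matrix")) D <- D$patches
  if (is.null(grid))
    grid <- expand.grid(beta = c(0.1, 1, 3), lambda = c(1e-4, 1e-3),
                        rho = c(0.01, 0.05))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(D))))
  score_one <- function(beta, lambda, rho) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- D[fold_id != f, , drop = FALSE]
      te <- D[fold_id == f, , drop = FALSE]
      fit <- train_autoencoder(tr, k, rho, beta, lambda, seed = seed,
                               max_iter = max_iter)
      p <- fit$params
      H <- sigmoid(te %*% t(p$theta1) +
                     matrix(p$b1, nrow(te), k, byrow = TRUE))
      Xhat <- sigmoid(H %*% t(p$theta2) +
                        matrix(p$b2, nrow(te), ncol(te), byrow = TRUE))
      mean((te - Xhat)^2)
    }, numeric(1))
    mean(errs)
  }
  scores <- purrr::pmap_dbl(grid, score_one)
  out <- as_tibble(grid)
  out$cv_error <- scores
  list(best = out[which.min(scores), ], scores = out)
}
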