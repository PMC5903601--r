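#' Classifier specification
#'
#' Hyperparameter policy for the SVM stage: cost fixed at `C = 1`; for the
#' RBF kernel, gamma is chosen from `gamma_grid` (default
#' `{0.1 * 2^i | i = 0..10}`) by internal stratified 5-fold
#' cross-validation accuracy, ties broken toward the smallest gamma.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_margin SVM cost parameter (default 1).
#' @param gamma_grid Candidate gamma values (RBF only).
#' @param standardize Z-score features with training statistics.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel = c("linear", "rbf"), C_margin = 1,
                            gamma_grid = 0.1 * 2^(0:10),
                            standardize = TRUE) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, C_margin = C_margin,
                 gamma_grid = sort(gamma_grid), standardize = standardize),
            class = "classifier_spec")
}

as_label_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("control", "case"))
  if (any(is.na(f))) abort("labels must be 'case' or 'control'")
  f
}

#' Train an SVM under the package's hyperparameter policy
#'
#' Optionally z-scores features with training statistics, selects gamma by
#' internal stratified `cv_folds`-fold CV accuracy when the kernel is RBF
#' (ties go to the smallest gamma), and refits on all training data with
#' cost `C_margin`.
#'
#' @param features Subjects x features numeric matrix, finite.
#' @param labels Vector of `"case"` / `"control"`.
#' @param spec A [classifier_spec()].
#' @param cv_folds Internal CV folds for gamma selection (default 5; use
#'   `length(labels)` for leave-one-out).
#' @param seed Seed for the CV fold assignment.
#' @return Object of class `svm_fit` with the fitted model, the selected
#'   gamma, the CV table and the standardization statistics.
#' @export
train_svm <- function(features, labels, spec = classifier_spec(),
                      cv_folds = 5, seed = 1) {
  features <- as.matrix(features)
  stopifnot_finite(features, "`features`")
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2) abort("need both classes in the labels")
  ctr <- scl <- NULL
  if (spec$standardize) {
    ctr <- colMeans(features)
    scl <- apply(features, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    features <- scale(features, ctr, scl)
  }
  cv_table <- NULL
  gamma <- if (spec$kernel == "rbf") spec$gamma_grid[1] else NULL
  if (spec$kernel == "rbf" && length(spec$gamma_grid) > 1) {
    folds <- stratified_folds(y, min(cv_folds, length(y)), seed = seed)
    acc <- vapply(spec$gamma_grid, function(g) {
      correct <- 0L
      for (f in sort(unique(folds))) {
        tr <- folds != f
        if (nlevels(droplevels(y[tr])) < 2) next
        m <- e1071::svm(features[tr, , drop = FALSE], y[tr],
                        kernel = "radial", gamma = g,
                        cost = spec$C_margin, scale = FALSE)
        p <- predict(m, features[!tr, , drop = FALSE])
        correct <- correct + sum(p == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    cv_table <- tibble(gamma = spec$gamma_grid, cv_accuracy = acc)
    gamma <- spec$gamma_grid[which.max(acc)]     # ties: smallest (sorted)
  }
  model <- if (spec$kernel == "rbf")
    e1071::svm(features, y, kernel = "radial", gamma = gamma,
               cost = spec$C_margin, scale = FALSE)
  else
    e1071::svm(features, y, kernel = "linear", cost = spec$C_margin,
               scale = FALSE)
  structure(list(model = model, spec = spec, gamma = gamma,
                 cv_table = cv_table, center = ctr, scale = scl,
                 levels = levels(y)),
            class = "svm_fit")
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$center))
    newdata <- scale(newdata, object$center, object$scale)
  predict(object$model, newdata)
}

#' Cross-validated accuracy of the SVM policy
#'
#' Stratified `folds`-fold cross-validation of the full training policy
#' (including any internal gamma selection on each training fold).
#'
#' @inheritParams train_svm
#' @param folds Outer CV folds (default 5).
#' @return List with `accuracy` and the out-of-fold `predictions`.
#' @export
cv_accuracy <- function(features, labels, spec = classifier_spec(),
                        folds = 5, seed = 1) {
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  fid <- stratified_folds(y, folds, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(fid))) {
    tr <- fid != f
    fit <- train_svm(features[tr, , drop = FALSE], y[tr], spec,
                     seed = seed + f)
    pred[!tr] <- predict(fit, features[!tr, , drop = FALSE])
  }
  list(accuracy = mean(pred == y), predictions = pred, truth = y)
}

#' Combine structural and functional feature blocks
#'
#' Horizontal concatenation with the structural (MRI) block first; both
#' blocks must list subjects in the same order.
#'
#' @param mri n x f1 matrix.
#' @param fmri n x f2 matrix.
#' @return n x (f1 + f2) matrix.
#' @export
combine_features <- function(mri, fmri) {
  mri <- as.matrix(mri); fmri <- as.matrix(fmri)
  if (nrow(mri) != nrow(fmri))
    abort("feature blocks disagree on the number of subjects")
  cbind(mri, fmri)
}

#' @export
tidy.svm_fit <- function(x, ...) {
  if (is.null(x$cv_table))
    tibble(gamma = NA_real_, cv_accuracy = NA_real_)
  else x$cv_table
}

#' @export
glance.svm_fit <- function(x, ...) {
  tibble(kernel = x$spec$kernel, cost = x$spec$C_margin,
         gamma = if (is.null(x$gamma)) NA_real_ else x$gamma,
         n_support = x$model$tot.nSV)
}
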