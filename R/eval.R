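#' Confusion-matrix evaluation of predictions
#'
#' Computes accuracy, sensitivity, specificity and Youden's J statistic
#' (`J = sensitivity + specificity - 1`) treating `"case"` as the positive
#' class, plus an exact one-sided binomial test of whether the number of
#' correct predictions exceeds what a `baseline_rate` coin would produce:
#' `P(X >= n_correct | n_total, baseline_rate)`.
#'
#' @param pred,truth Equal-length vectors of `"case"` / `"control"`.
#' @param baseline_rate Baseline accuracy to test against; defaults to the
#'   majority-class rate of `truth`.
#' @return Object of class `eval_report` (see [tidy.eval_report()]).
#' @export
evaluate_predictions <- function(pred, truth, baseline_rate = NULL) {
  pred <- as_label_factor(pred)
  truth <- as_label_factor(truth)
  if (length(pred) != length(truth)) abort("`pred` and `truth` lengths differ")
  tp <- sum(pred == "case" & truth == "case")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "case" & truth == "control")
  fn <- sum(pred == "control" & truth == "case")
  n <- length(truth)
  if (is.null(baseline_rate))
    baseline_rate <- max(mean(truth == "case"), mean(truth == "control"))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  n_correct <- tp + tn
  structure(list(
    accuracy = n_correct / n, sensitivity = sens, specificity = spec,
    jstat = sens + spec - 1, n_correct = n_correct, n_total = n,
    binomial_p = pbinom(n_correct - 1, n, baseline_rate, lower.tail = FALSE),
    baseline_rate = baseline_rate,
    TP = tp, FP = fp, TN = tn, FN = fn),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> accuracy ", round(x$accuracy, 4),
      " (", x$n_correct, "/", x$n_total, "), sensitivity ",
      round(x$sensitivity, 4), ", specificity ", round(x$specificity, 4),
      ", Jstat ", round(x$jstat, 4),
      ", binomial p ", format(x$binomial_p, digits = 3),
      " vs baseline ", round(x$baseline_rate, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return `tidy()`: long tibble of metrics; `glance()`: one-row tibble.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "jstat",
                    "binomial_p"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$jstat,
                   x$binomial_p))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, jstat = x$jstat,
         n_correct = x$n_correct, n_total = x$n_total,
         binomial_p = x$binomial_p, baseline_rate = x$baseline_rate,
         TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN)
}

#' Export an evaluation report as JSON
#'
#' @param x An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Exact McNemar test between two prediction vectors
#'
#' Counts the discordant pairs (`b`: A correct and B wrong, `c`: the
#' reverse) and performs the exact two-sided binomial test of `b` against
#' `Binomial(b + c, 1/2)`. Returns `p = 1` when there are no discordant
#' pairs.
#'
#' @param pred_a,pred_b,truth Equal-length label vectors.
#' @return The exact two-sided p-value.
#' @export
mcnemar_test <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth))
    abort("prediction and truth lengths differ")
  ca <- pred_a == truth
  cb <- pred_b == truth
  b <- sum(ca & !cb)
  c <- sum(!ca & cb)
  if (b + c == 0) return(1)
  stats::binom.test(b, b + c, 0.5)$p.value
}

#' Permutation test of classifier accuracy
#'
#' Each iteration permutes the subject labels (class counts preserved),
#' draws a fresh stratified train/test split, trains via `train_fn` on the
#' training part and measures test accuracy; the observed accuracy uses
#' the unpermuted labels under the same split protocol. The p-value is the
#' add-one rank `(count(null >= observed) + 1) / (iters + 1)`.
#'
#' @param features Subjects x features matrix.
#' @param labels `"case"` / `"control"` vector.
#' @param train_fn Function `(features, labels) -> model` whose
#'   `predict(model, newdata)` returns labels; defaults to a linear SVM
#'   via [train_svm()].
#' @param iters Number of permutations (default 1000).
#' @param train_frac Training fraction of each split (default 0.7).
#' @param n_splits Random splits averaged per accuracy evaluation (default
#'   1). Averaging over several splits makes the statistic finer-grained,
#'   reducing the accuracy ties that otherwise make the add-one p-value
#'   conservative on small test sets.
#' @param seed RNG seed.
#' @return Object of class `permutation_result` with `null_accuracies`,
#'   `observed`, `p_value`, `iters`.
#' @export
permutation_test <- function(features, labels, train_fn = NULL,
                             iters = 1000, train_frac = 0.7, n_splits = 1,
                             seed = 1) {
  if (iters < 1) abort("`iters` must be >= 1")
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  if (is.null(train_fn))
    train_fn <- function(f, l) train_svm(f, l, classifier_spec("linear"))
  split_accuracy <- function(lab) {
    one <- function() {
      idx_tr <- unlist(lapply(levels(lab), function(cl) {
        i <- which(lab == cl)
        sample(i, max(1L, round(train_frac * length(i))))
      }))
      te <- setdiff(seq_along(lab), idx_tr)
      m <- train_fn(features[idx_tr, , drop = FALSE], lab[idx_tr])
      mean(predict(m, features[te, , drop = FALSE]) == lab[te])
    }
    mean(vapply(seq_len(n_splits), function(s) one(), numeric(1)))
  }
  with_seed(seed, {
    observed <- split_accuracy(y)
    null_acc <- vapply(seq_len(iters), function(i)
      split_accuracy(sample(y)), numeric(1))
    structure(list(null_accuracies = null_acc, observed = observed,
                   p_value = (sum(null_acc >= observed) + 1) / (iters + 1),
                   iters = iters),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed accuracy ", round(x$observed, 4),
      ", null mean ", round(mean(x$null_accuracies), 4),
      ", p = ", format(x$p_value, digits = 3),
      " (", x$iters, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(iteration = seq_along(x$null_accuracies),
         null_accuracy = x$null_accuracies)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, iters = x$iters,
         null_mean = mean(x$null_accuracies),
         null_sd = sd(x$null_accuracies))
}

#' Site-balanced subsampling of a cohort
#'
#' Within each site, subsamples the majority class down to the minority
#' class count (seeded), so the case:control ratio is 50:50 per site.
#' Sites lacking either class contribute nothing.
#'
#' @param cohort A cohort tibble with `site` and `label` columns.
#' @param seed RNG seed for the subsampling draws.
#' @return The subsampled cohort tibble.
#' @export
site_balanced_subsets <- function(cohort, seed = 1) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$site),
      function(idx) {
        cases <- idx[cohort$label[idx] == "case"]
        ctrls <- idx[cohort$label[idx] == "control"]
        m <- min(length(cases), length(ctrls))
        if (m == 0) return(integer(0))
        c(if (length(cases) > m) sample(cases, m) else cases,
          if (length(ctrls) > m) sample(ctrls, m) else ctrls)
      }))
    cohort[sort(keep), , drop = FALSE]
  })
}

#' Site-only confound model
#'
#' Describes each subject by a one-hot encoding of their site and runs the
#' linear-SVM path under stratified cross-validation, reporting how
#' accurately disease status can be predicted from site membership alone
#' (a confound ceiling). Degenerate designs (a single site, or a single
#' class) fall back to the majority-class rate.
#'
#' @param cohort Cohort tibble with a `site` column.
#' @param labels Label vector; defaults to `cohort$label`.
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @return An [evaluate_predictions()] report.
#' @export
site_only_model <- function(cohort, labels = cohort$label, folds = 5,
                            seed = 1) {
  y <- as_label_factor(labels)
  sites <- factor(cohort$site)
  majority <- names(which.max(table(y)))
  if (nlevels(droplevels(sites)) < 2 || nlevels(droplevels(y)) < 2) {
    pred <- factor(rep(majority, length(y)), levels = levels(y))
    return(evaluate_predictions(pred, y))
  }
  X <- stats::model.matrix(~ sites - 1)
  cv <- cv_accuracy(X, y, classifier_spec("linear", standardize = FALSE),
                    folds = folds, seed = seed)
  evaluate_predictions(cv$predictions, cv$truth)
}

#' Per-timepoint group comparison of one component's weights
#'
#' For a chosen component `h`, compares case and control group means of
#' the time-course weight `A_i[t, h]` at every time point with a Welch
#' two-sample t-test (no multiplicity correction), and counts (i) time
#' points where the case mean is below the control mean and (ii) time
#' points with `p <= alpha`.
#'
#' @param timecourses List of T x C [back_reconstruct()] matrices, one per
#'   subject, sharing T.
#' @param labels `"case"` / `"control"` per subject.
#' @param component Component index `h`.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `component_comparison` with `n_reduced`,
#'   `n_significant`, `n_timepoints` and a per-timepoint tibble.
#' @export
component_group_comparison <- function(timecourses, labels, component,
                                       alpha = 0.05) {
  y <- as_label_factor(labels)
  if (sum(y == "case") < 2 || sum(y == "control") < 2)
    abort("each group needs at least 2 subjects")
  Ts <- vapply(timecourses, nrow, integer(1))
  if (length(unique(Ts)) != 1L) abort("subjects disagree on T")
  W <- t(vapply(timecourses, function(a) a[, component], numeric(Ts[1])))
  if (sd(W[y == "case", ]) < 1e-14 || sd(W[y == "control", ]) < 1e-14)
    abort("zero-variance component")
  per_t <- purrr::map_dfr(seq_len(ncol(W)), function(t) {
    ca <- W[y == "case", t]; co <- W[y == "control", t]
    tt <- t.test(ca, co)
    tibble(timepoint = t, case_mean = mean(ca), control_mean = mean(co),
           p_value = tt$p.value)
  })
  structure(list(
    n_reduced = sum(per_t$case_mean < per_t$control_mean),
    n_significant = sum(per_t$p_value <= alpha),
    n_timepoints = ncol(W), alpha = alpha, per_timepoint = per_t,
    component = component),
    class = "component_comparison")
}

#' @export
print.component_comparison <- function(x, ...) {
  cat("<component_comparison> component ", x$component, ": case mean below",
      " control at ", x$n_reduced, "/", x$n_timepoints, " time points; ",
      x$n_significant, " significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.component_comparison <- function(x, ...) x$per_timepoint

#' @export
glance.component_comparison <- function(x, ...) {
  tibble(component = x$component, n_reduced = x$n_reduced,
         n_significant = x$n_significant, n_timepoints = x$n_timepoints,
         alpha = x$alpha)
}
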