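#' @export
tidy.nsd_model <- function(x, ...) {
  tibble(sweep = seq_along(x$objective_trace) - 1L,
         objective = x$objective_trace)
}

#' @export
glance.nsd_model <- function(x, ...) {
  tibble(K = x$K, C = x$C, n_sweeps = length(x$objective_trace) - 1L,
         final_objective = x$objective_trace[length(x$objective_trace)],
         converged = x$converged)
}

#' Plot the NSD fit objective trace
#'
#' @param object A fitted [fit_nsd()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nsd_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = "covariance-matching objective",
                  title = "Non-stationary decomposition fit") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the null accuracies with the observed accuracy marked.
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "accuracy under permuted labels", y = "count",
                  title = sprintf("Permutation test (p = %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-timepoint group-comparison p-values
#'
#' @param object A [component_group_comparison()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.component_comparison <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$timepoint, y = .data$p_value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$case_mean <
                                       .data$control_mean)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time point", y = "Welch t-test p-value",
                  colour = "case mean lower",
                  title = sprintf("Component %d group comparison",
                                  object$component)) +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics as a bar chart
#'
#' @param object An [evaluate_predictions()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$metric != "binomial_p", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$baseline_rate,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = NULL, title = "Classifier evaluation",
                  subtitle = "dashed line: baseline accuracy") +
    ggplot2::theme_minimal()
}

#' Export spatial maps as NIfTI volumes
#'
#' Scatters each row of the map matrix back into the mask and writes one
#' 3D NIfTI per component, for visual inspection in a standard viewer.
#'
#' @param maps A [spatial_maps()] with a mask, or a C x V matrix plus
#'   `mask`.
#' @param mask Logical 3D array (used when `maps` carries none).
#' @param dir Output directory.
#' @return Character vector of written paths.
#' @export
write_spatial_maps <- function(maps, mask = NULL, dir = tempfile("maps")) {
  S <- if (inherits(maps, "spatial_maps")) maps$S else maps
  if (is.null(mask) && inherits(maps, "spatial_maps")) mask <- maps$mask
  if (is.null(mask)) abort("a mask is required to export spatial maps")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- scatter_to_mask(S, mask)
  vapply(seq_len(nrow(S)), function(h) {
    p <- file.path(dir, sprintf("component_%02d.nii.gz", h))
    write_volume(volume3d(frames[[h]]), p)
    p
  }, character(1))
}
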