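#' Construct a BOLD series
#'
#' One subject's functional data as a T x V matrix over a voxel mask
#' (columns in fixed scan order: first array index fastest), together with
#' subject metadata.
#'
#' @param data Numeric T x V matrix, T >= 2, finite.
#' @param mask Logical 3D array with V `TRUE` voxels.
#' @param subject_id,site,label Subject metadata strings.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, mask, subject_id = NA_character_,
                        site = NA_character_, label = NA_character_) {
  if (!is.matrix(data)) abort("`data` must be a T x V matrix")
  if (nrow(data) < 2L) abort("a BOLD series needs at least 2 time points")
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    abort("`mask` must be a logical 3D array")
  if (sum(mask) != ncol(data))
    abort("mask voxel count does not match the number of data columns")
  stopifnot_finite(data, "`data`")
  structure(
    list(data = data, mask = mask, t_common = nrow(data),
         subject_id = subject_id, site = site, label = label),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> ", x$subject_id, ": ", nrow(x$data), " time points x ",
      ncol(x$data), " voxels (site ", x$site, ", label ", x$label, ")\n",
      sep = "")
  invisible(x)
}

#' Vectorize a frame list into a BOLD series
#'
#' Stacks masked voxel intensities of each frame into a T x V matrix with
#' T = `t_common`. Columns follow the fixed scan order of the mask (first
#' array index fastest). Series longer than `t_common` are truncated by
#' default, or linearly resampled to length `t_common` when
#' `method = "resample"`.
#'
#' @param frames List of [volume3d()] (or 3D arrays) sharing dimensions
#'   with `mask`, in acquisition order.
#' @param mask Logical 3D array; `TRUE` marks retained voxels.
#' @param t_common Number of time points to retain (>= 2, <= length(frames)).
#' @param method `"truncate"` (default) or `"resample"`.
#' @param ... Metadata passed to [bold_series()].
#' @return A `bold_series`.
#' @export
vectorize_series <- function(frames, mask, t_common = length(frames),
                             method = c("truncate", "resample"), ...) {
  method <- match.arg(method)
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) abort("degenerate input: mask has no TRUE voxels")
  if (t_common < 2L) abort("`t_common` must be >= 2")
  if (t_common > length(frames))
    abort("`t_common` exceeds the number of frames")
  arrs <- lapply(frames, as_volume_array)
  if (!all(vapply(arrs, function(a) identical(dim(a), dim(mask)), logical(1))))
    abort("all frames must share dimensions with the mask")
  idx <- which(mask)
  full <- do.call(rbind, lapply(arrs, function(a) a[idx]))
  data <- if (method == "truncate" || length(frames) == t_common) {
    full[seq_len(t_common), , drop = FALSE]
  } else {
    at <- seq(1, nrow(full), length.out = t_common)
    apply(full, 2, function(col) stats::approx(seq_len(nrow(full)), col,
                                               xout = at)$y)
  }
  bold_series(data, mask, ...)
}

#' Scatter a T x V matrix back into volume frames
#'
#' Inverse of the masking step of [vectorize_series()]: voxels outside the
#' mask are filled with `fill`.
#'
#' @param data T x V matrix.
#' @param mask Logical 3D array with V `TRUE` voxels.
#' @param fill Value for voxels outside the mask.
#' @return List of 3D arrays.
#' @export
scatter_to_mask <- function(data, mask, fill = 0) {
  idx <- which(mask)
  lapply(seq_len(nrow(data)), function(t) {
    a <- array(fill, dim(mask)); a[idx] <- data[t, ]; a
  })
}

cohort_required_cols <- c("subject_id", "label", "site", "split",
                          "structural_path", "functional_path")

#' Load and validate a cohort table
#'
#' Reads a TSV with the exact header
#' `subject_id label site split structural_path functional_path`,
#' validates it (unique ids, labels in case/control, split in
#' train/holdout, referenced files present) and returns a tibble.
#'
#' @param table_path Path to the TSV.
#' @param check_files Verify that referenced files exist (default `TRUE`).
#' @return A tibble with class `cohort_table`.
#' @export
load_cohort <- function(table_path, check_files = TRUE) {
  tab <- readr::read_tsv(table_path, col_types = readr::cols(
    .default = readr::col_character()))
  validate_cohort(tab, check_files = check_files)
}

#' Validate an in-memory cohort table
#'
#' @param tab A data frame with the cohort columns.
#' @inheritParams load_cohort
#' @return The validated tibble, classed `cohort_table`.
#' @export
validate_cohort <- function(tab, check_files = FALSE) {
  missing_cols <- setdiff(cohort_required_cols, names(tab))
  if (length(missing_cols) > 0)
    abort(paste("cohort table is missing columns:",
                paste(missing_cols, collapse = ", ")))
  tab <- as_tibble(tab)[, cohort_required_cols]
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup) > 0)
    abort(paste("duplicate subject_id:", paste(unique(dup), collapse = ", ")))
  bad_lab <- which(!tab$label %in% c("case", "control"))
  if (length(bad_lab) > 0)
    abort(paste0("unknown label '", tab$label[bad_lab[1]], "' in row ",
                 bad_lab[1], " (subject ", tab$subject_id[bad_lab[1]], ")"))
  bad_split <- which(!tab$split %in% c("train", "holdout"))
  if (length(bad_split) > 0)
    abort(paste0("unknown split '", tab$split[bad_split[1]], "' in row ",
                 bad_split[1]))
  if (check_files) {
    for (col in c("structural_path", "functional_path")) {
      paths <- tab[[col]]
      missing <- paths[!is.na(paths) & nzchar(paths) & !file.exists(paths)]
      if (length(missing) > 0)
        abort(paste("missing file:", missing[1]))
    }
  }
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Write a cohort table as TSV
#'
#' @param tab A cohort tibble.
#' @param path Output path.
#' @export
write_cohort <- function(tab, path) {
  readr::write_tsv(tab[, cohort_required_cols], path)
  invisible(path)
}
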