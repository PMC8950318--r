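#' Quantile-normalize a sample table
#'
#' Forces every sample's intensity distribution onto the across-sample mean
#' of sorted intensity vectors, the standard remedy for batch-to-batch
#' distributional shifts in LC-MS feature tables. Ties within a sample are
#' assigned the mean of the reference values at their tied ranks.
#' The operation is idempotent. Delegates to
#' [limma::normalizeQuantiles()] on the transposed intensity matrix.
#'
#' @param table A [sample_table()].
#' @return The sample table with normalized feature columns; metadata
#'   untouched.
#' @examples
#' tbl <- sample_table(tibble::tibble(
#'   sample_id = c("a", "b"), dose = 0, time = 0, donor = "d1", batch = "b1",
#'   F1 = c(2, 1), F2 = c(4, 5), F3 = c(6, 9)
#' ))
#' quantile_normalize(tbl)[c("F1", "F2", "F3")]
#' @export
quantile_normalize <- function(table) {
  table <- sample_table(table)
  m <- intensity_matrix(table)
  if (any(rowSums(m) == 0)) abort("a sample is entirely zero")
  norm <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  table[colnames(m)] <- as_tibble(norm)
  table
}

#' Per-condition log2 fold changes against unstimulated controls
#'
#' For every (dose, time) condition, computes
#' `log2((mean treated + pseudo) / (mean dose-0 same-time + pseudo))`
#' per feature, with means taken across donors. The dose-0 reference rows
#' are included and are identically 0.
#'
#' @param table A [sample_table()]; dose-0 samples must exist at every time
#'   point present.
#' @param pseudo Pseudo-intensity added to both means to keep the log
#'   finite in the presence of zeros. Default: half the smallest nonzero
#'   intensity in the table.
#' @return A tibble `feature`, `dose`, `time`, `lfc` (long format; use
#'   [profile_matrix()] to reshape for clustering).
#' @examples
#' tbl <- sample_table(tibble::tibble(
#'   sample_id = c("c", "t"), dose = c(0, 5), time = 4,
#'   donor = "d1", batch = "b1", F1 = c(2, 8)
#' ))
#' log2_fold_change(tbl, pseudo = 0)
#' @export
log2_fold_change <- function(table, pseudo = NULL) {
  table <- sample_table(table)
  m <- intensity_matrix(table)
  if (is.null(pseudo)) {
    nz <- m[m > 0]
    pseudo <- if (length(nz) > 0) min(nz) / 2 else 0
  }
  if (!all(unique(table$time) %in% table$time[table$dose == 0])) {
    abort("missing dose-0 reference samples at some time point")
  }

  means <- dplyr::bind_cols(table[c("dose", "time")], as_tibble(m)) |>
    dplyr::group_by(.data$dose, .data$time) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-c("dose", "time"), names_to = "feature",
                        values_to = "mean_intensity")

  ref <- means |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::select("time", "feature", ref_intensity = "mean_intensity")

  means |>
    dplyr::inner_join(ref, by = c("time", "feature")) |>
    dplyr::mutate(lfc = log2((.data$mean_intensity + pseudo) /
                               (.data$ref_intensity + pseudo))) |>
    dplyr::select("feature", "dose", "time", "lfc") |>
    dplyr::arrange(.data$feature, .data$time, .data$dose)
}

#' Reshape a long fold-change table into a feature-by-condition matrix
#'
#' Keeps treated conditions only (dose > 0, time > 0), the columns
#' clustering operates on.
#'
#' @param fc Output of [log2_fold_change()].
#' @param features Optional subset of features to keep, in order.
#' @return Numeric matrix, features in rows, `dose<d>_t<t>` columns.
#' @export
profile_matrix <- function(fc, features = NULL) {
  fc <- dplyr::filter(fc, .data$dose > 0, .data$time > 0)
  if (!is.null(features)) {
    fc <- dplyr::filter(fc, .data$feature %in% features)
  }
  wide <- fc |>
    dplyr::mutate(condition = sprintf("dose%s_t%s", .data$dose, .data$time)) |>
    dplyr::select("feature", "condition", "lfc") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "lfc")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$feature
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  m
}
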