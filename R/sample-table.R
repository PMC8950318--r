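#' Sample-by-feature intensity tables
#'
#' A *sample table* is a tibble with one row per LC-MS sample. The reserved
#' metadata columns are `sample_id`, `dose` (µM), `time` (h), `donor` and
#' `batch`; every remaining numeric column is a metabolic feature (an m/z
#' peak) holding non-negative intensities in arbitrary units.
#'
#' `sample_table()` validates a data frame and returns it as a tibble;
#' `feature_cols()` returns the feature column names.
#'
#' @param x A data frame with the reserved metadata columns plus one numeric
#'   column per feature.
#' @return `sample_table()` returns the validated tibble; `feature_cols()` a
#'   character vector of feature column names.
#' @examples
#' tbl <- sample_table(tibble::tibble(
#'   sample_id = c("s1", "s2"), dose = c(0, 5), time = 4,
#'   donor = "d1", batch = "b1", F001 = c(10, 40), F002 = c(3, 3)
#' ))
#' feature_cols(tbl)
#' @export
sample_table <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(sample_meta_cols(), names(x))
  if (length(missing) > 0) {
    abort(paste0("sample table lacks metadata column(s): ",
                 paste(missing, collapse = ", ")))
  }
  feats <- feature_cols(x)
  if (length(feats) == 0) abort("sample table has no feature columns")
  if (anyDuplicated(feats)) {
    abort(paste0("duplicated feature id: ", feats[duplicated(feats)][1]))
  }
  if (anyDuplicated(x$sample_id)) abort("duplicated sample_id")
  mat <- as.matrix(x[feats])
  if (!is.numeric(mat)) abort("non-numeric intensity values in feature columns")
  if (any(!is.finite(mat))) abort("non-finite intensity values")
  if (any(mat < 0)) abort("negative intensity values")
  x
}

sample_meta_cols <- function() c("sample_id", "dose", "time", "donor", "batch")

#' @rdname sample_table
#' @export
feature_cols <- function(x) {
  setdiff(names(x), sample_meta_cols())
}

#' Extract the intensity matrix of a sample table
#'
#' @param x A sample table (see [sample_table()]).
#' @return A numeric matrix, samples in rows (named by `sample_id`),
#'   features in columns.
#' @export
intensity_matrix <- function(x) {
  m <- as.matrix(x[feature_cols(x)])
  rownames(m) <- x$sample_id
  m
}

#' Read or write a sample table
#'
#' Plain-text I/O for sample tables. The delimiter is inferred from the file
#' extension (`.csv` comma, `.tsv`/`.txt` tab). A written table reads back
#' losslessly at 12 significant digits.
#'
#' @param path File path ending in `.csv` or `.tsv`.
#' @param x A sample table.
#' @return `read_sample_table()` returns a validated sample table;
#'   `write_sample_table()` returns `path` invisibly.
#' @export
read_sample_table <- function(path) {
  sample_table(read_delim_auto(path))
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(x, path) {
  write_delim_auto(sample_table(x), path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input file: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

write_delim_auto <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}
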