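# Events-by-timepoints matrices are wide tibbles: an id column first, then
# one numeric column per timepoint in the design's order. The metric tag
# and the pseudo-count used are carried as attributes.

new_splicing_matrix <- function(wide, metric, pseudo) {
  attr(wide, "metric") <- metric
  attr(wide, "pseudo") <- pseudo
  class(wide) <- unique(c("splicing_matrix", class(wide)))
  wide
}

#' Convert a splicing matrix tibble to a numeric matrix
#'
#' @param x A wide tibble whose first column holds row ids and remaining
#'   columns are timepoints.
#' @return A numeric matrix with row names from the id column.
#' @export
matrix_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a splicing matrix to TSV
#'
#' Missing cells are written as `NA`.
#'
#' @param x Wide matrix tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}

#' @export
print.splicing_matrix <- function(x, ...) {
  cat(sprintf("# %s matrix: %d rows x %d timepoints (pseudo-count %g)\n",
              attr(x, "metric") %||% "splicing", nrow(x), ncol(x) - 1L,
              attr(x, "pseudo") %||% NA_real_))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
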