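#' Coerce a samples-by-variables table to a numeric data matrix
#'
#' Expression and abundance tables come as data frames with one row per
#' sample and one column per variable (gene, transcript, metabolite), often
#' with a leading column of sample identifiers. `as_data_matrix()` turns such
#' a table (or a plain matrix) into the validated numeric matrix the fitting
#' functions work on: rownames carry sample identifiers, colnames carry
#' variable names, and a `"centered"` attribute records the centering state.
#'
#' Missing and non-finite values are rejected (impute upstream if needed);
#' the error names the offending column.
#'
#' @param x a data frame, tibble or numeric matrix; for data frames a single
#'   non-numeric leading column is interpreted as sample identifiers.
#' @param sample_col optional name of the identifier column; by default the
#'   first non-numeric column is used when present.
#' @return a numeric matrix with sample identifiers as rownames, variable
#'   names as colnames and a logical `"centered"` attribute.
#' @examples
#' df <- data.frame(sample = c("a", "b", "c"), g1 = 1:3, g2 = c(2, 1, 0))
#' as_data_matrix(df)
#' @export
as_data_matrix <- function(x, sample_col = NULL) {
  if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x)
    if (is.null(sample_col)) {
      non_num <- which(!vapply(df, is.numeric, logical(1)))
      if (length(non_num) > 1L) {
        abort(sprintf("multiple non-numeric columns (%s); name the sample-id column via `sample_col`.",
                      paste(names(df)[non_num], collapse = ", ")))
      }
      sample_col <- if (length(non_num) == 1L) names(df)[non_num] else NULL
    }
    ids <- NULL
    if (!is.null(sample_col)) {
      if (!sample_col %in% names(df)) {
        abort(sprintf("sample-id column '%s' not found.", sample_col))
      }
      ids <- as.character(df[[sample_col]])
      df[[sample_col]] <- NULL
    }
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    abort("`x` must be a matrix or data frame.")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 samples and 2 variables.")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("duplicate variable names: %s",
                  paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  bad <- !apply(is.finite(m), 2, all)
  if (any(bad)) {
    abort(sprintf("missing or non-finite values in column(s): %s",
                  paste(colnames(m)[bad], collapse = ", ")))
  }
  mu <- colMeans(m)
  scale_ref <- pmax(apply(abs(m), 2, max), 1)
  attr(m, "centered") <- all(abs(mu) <= 1e-10 * scale_ref)
  m
}

#' Center the columns of a data matrix
#'
#' Subtracts the column mean from every variable, the standard preprocessing
#' for SVD-based decompositions. Idempotent: centering an already-centered
#' matrix returns it unchanged (up to floating point).
#'
#' @param x a matrix or data frame accepted by [as_data_matrix()].
#' @inheritParams as_data_matrix
#' @return the centered matrix, with the `"centered"` attribute set.
#' @examples
#' center_columns(matrix(c(1, 2, 3, 4, 6, 8), ncol = 2))
#' @export
center_columns <- function(x, sample_col = NULL) {
  m <- as_data_matrix(x, sample_col = sample_col)
  out <- sweep(m, 2, colMeans(m), `-`)
  attr(out, "centered") <- TRUE
  out
}

## internal: centered matrix + means, single pass used by all fitters
center_info <- function(x, sample_col = NULL) {
  m <- as_data_matrix(x, sample_col = sample_col)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu, `-`)
  attr(xc, "centered") <- TRUE
  list(xc = xc, means = mu,
       sample_ids = rownames(m), variable_names = colnames(m))
}
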