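#' Read a samples-by-variables matrix from a delimited file
#'
#' Expects a rectangular numeric table with a header row of variable names
#' and a first column of sample identifiers (the layout written by
#' [write_results()] and by most expression-matrix exports). The delimiter
#' is inferred from the extension (`.csv` comma, `.tsv`/`.txt` tab) unless
#' given. An optional label column (known biological condition per sample)
#' can be split off for cluster validation.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` infers from the extension.
#' @param labels_column optional name of a column holding sample class
#'   labels.
#' @return a list with `data` (numeric matrix, sample ids as rownames) and
#'   `labels` (factor or NULL).
#' @export
read_matrix <- function(path, delimiter = NULL, labels_column = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed table: %s (row %s, column %s)",
                  probs$expected[1], probs$row[1], probs$col[1]))
  }
  df <- as.data.frame(df)
  if (ncol(df) < 2L) abort("need a sample-id column plus at least one variable.")
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  labels <- NULL
  if (!is.null(labels_column)) {
    if (!labels_column %in% names(df)) {
      abort(sprintf("label column '%s' not found.", labels_column))
    }
    labels <- factor(df[[labels_column]])
    df[[labels_column]] <- NULL
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    col <- names(df)[bad[1]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad[1]]]))))[1]
    abort(sprintf("non-numeric value in column '%s' (row %s).", col,
                  ifelse(is.na(row), "?", row)))
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  list(data = as_data_matrix(m), labels = labels)
}

#' Write a fitted decomposition (or replicate report) to a directory
#'
#' For a fit (`pca_fit`, `ipca_fit`, `sipca_fit`, `ica_fit`, `spca_fit`)
#' writes `scores.csv` (samples x components), `loadings.csv` (variables x
#' components), `kurtosis.json` (per-component kurtosis, ordering and any
#' sparsity plan) and `run_log.json` (method, settings, seed). For a
#' [run_replicates()] report writes `replicates.csv` (one row per
#' replicate x method x metric x component) and `summary.json`.
#' Numeric round-trips through [read_matrix()] are exact to at least 1e-12.
#'
#' @param result a fitted object or `replicate_report`.
#' @param outdir output directory (created if missing).
#' @return (invisibly) the paths written.
#' @export
write_results <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create directory: %s", outdir))
  paths <- character()
  wjson <- function(x, f) {
    jsonlite::write_json(x, file.path(outdir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    paths <<- c(paths, file.path(outdir, f))
  }
  wcsv <- function(m, f, id_col) {
    df <- tibble::as_tibble(as.data.frame(m), rownames = id_col)
    readr::write_csv(df, file.path(outdir, f))
    paths <<- c(paths, file.path(outdir, f))
  }
  if (inherits(result, "replicate_report")) {
    if (is.null(result$replicates)) {
      abort("report was run with keep_replicates = FALSE; nothing to write.")
    }
    readr::write_csv(result$replicates, file.path(outdir, "replicates.csv"))
    paths <- c(paths, file.path(outdir, "replicates.csv"))
    wjson(list(design = unclass(result$design), methods = result$methods,
               n_reps = result$n_reps, n_failed = result$n_failed,
               seed = result$seed, keepX = result$keepX,
               summary = result$summary),
          "summary.json")
  } else if (inherits(result, c("pca_fit", "ipca_fit", "ica_fit",
                                "spca_fit"))) {
    wcsv(result$scores, "scores.csv", "sample")
    wcsv(result$loadings, "loadings.csv", "variable")
    kur <- if (inherits(result, "pca_fit")) {
      list(explained_variance = result$explained_variance[seq_len(result$ncomp)])
    } else if (inherits(result, "ica_fit")) {
      list(kurtosis = result$kurtosis, loading_kurtosis = result$loading_kurtosis,
           order = result$order)
    } else if (inherits(result, "spca_fit")) {
      list(keepX = result$keepX, gamma = result$gamma,
           selected = result$selected)
    } else {
      c(list(kurtosis = result$kurtosis, order = result$order),
        if (!is.null(result$keepX)) list(keepX = result$keepX,
                                         gamma = result$gamma,
                                         selected = result$selected))
    }
    wjson(kur, "kurtosis.json")
    wjson(list(class = class(result)[1],
               seed = result$seed %||% NULL,
               settings = result[intersect(names(result),
                 c("ncomp", "keepX", "contrast", "n_whiten", "scale"))]),
          "run_log.json")
  } else {
    abort("unsupported result type.")
  }
  invisible(paths)
}
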