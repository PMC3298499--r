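#' Tidy a fitted decomposition
#'
#' Returns the loading matrix in long form: one row per variable x
#' component, with columns `component`, `variable` and `loading`
#' (plus `selected` for sparse fits).
#'
#' @param x a `pca_fit`, `ipca_fit`, `sipca_fit`, `ica_fit` or `spca_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ipca_fit <- function(x, ...) {
  out <- tidy_loadings(x$loadings)
  if (!is.null(x$keepX)) out$selected <- out$loading != 0
  out
}

#' @rdname tidy.ipca_fit
#' @export
tidy.pca_fit <- function(x, ...) tidy_loadings(x$loadings)

#' @rdname tidy.ipca_fit
#' @export
tidy.ica_fit <- function(x, ...) tidy_loadings(x$loadings)

#' @rdname tidy.ipca_fit
#' @export
tidy.spca_fit <- function(x, ...) {
  out <- tidy_loadings(x$loadings)
  out$selected <- out$loading != 0
  out
}

#' @rdname tidy.ipca_fit
#' @export
tidy.replicate_report <- function(x, ...) x$summary

tidy_loadings <- function(l) {
  tibble::as_tibble(as.data.frame(l), rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading") |>
    dplyr::arrange(.data$component, .data$variable)
}

#' One-row summary of a fitted decomposition
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return a one-row tibble with the component count, convergence state and
#'   headline per-fit statistics (leading kurtosis or explained variance).
#' @export
glance.ipca_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp,
                 kurtosis_1 = x$kurtosis[1],
                 kurtosis_min = min(x$kurtosis),
                 sparse = !is.null(x$keepX),
                 converged = x$converged,
                 n_iterations = x$n_iterations)
}

#' @rdname glance.ipca_fit
#' @export
glance.pca_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp,
                 explained_variance = sum(x$explained_variance[seq_len(x$ncomp)]))
}

#' @rdname glance.ipca_fit
#' @export
glance.ica_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n_whiten = x$n_whiten,
                 kurtosis_1 = x$kurtosis[1], converged = x$converged,
                 n_iterations = x$n_iterations)
}

#' @rdname glance.ipca_fit
#' @export
glance.spca_fit <- function(x, ...) {
  tibble::tibble(ncomp = length(x$keepX),
                 keepX = paste(x$keepX, collapse = ","),
                 converged = all(x$converged),
                 max_iterations = max(x$iterations))
}

#' @rdname glance.ipca_fit
#' @export
glance.replicate_report <- function(x, ...) {
  tibble::tibble(case = x$design$case, n_reps = x$n_reps,
                 n_failed = x$n_failed, methods = paste(x$methods,
                                                        collapse = ","))
}

#' Component scores as a tibble
#'
#' @param x a fitted decomposition.
#' @param labels optional per-sample labels to carry along.
#' @return a tibble with `sample`, one column per component, and optionally
#'   `label`.
#' @export
score_table <- function(x, labels = NULL) {
  out <- tibble::as_tibble(as.data.frame(x$scores), rownames = "sample")
  if (!is.null(labels)) out$label <- labels
  out
}
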