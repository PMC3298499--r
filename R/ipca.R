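#' Independent principal component analysis
#'
#' IPCA denoises PCA loading vectors instead of the data or the scores:
#' the leading SVD loading vectors are standardized and passed to FastICA
#' as signals over the variables, producing independent loading vectors
#' whose distribution is pushed toward the spiky (super-Gaussian) shape
#' expected of a noiseless loading vector — a few variables with large
#' weights, the rest near zero. The independent principal components (IPCs)
#' are the projections of the centered data onto these loadings, and
#' components are ordered by the excess kurtosis of their loading vectors,
#' largest first: a sudden drop in the kurtosis sequence marks the point
#' where further components carry no non-Gaussian structure.
#'
#' @param data samples-by-variables matrix or data frame
#'   (see [as_data_matrix()]).
#' @param ncomp number of components, between 2 and `min(n, p)` (FastICA
#'   needs at least two signals).
#' @param contrast,tol,max_iter,n_restarts,seed FastICA options, see
#'   [fast_ica()].
#' @inheritParams as_data_matrix
#' @return an object of class `ipca_fit`: `loadings` (p x ncomp, columns
#'   are kurtosis-ordered independent loading vectors with zero mean and
#'   unit population variance), `scores` (n x ncomp IPCs, the projection of
#'   the centered data on the loadings), `kurtosis` (non-increasing),
#'   `order` (permutation applied to the raw FastICA output), `center`,
#'   FastICA diagnostics, and naming metadata.
#' @examples
#' x <- matrix(rnorm(50 * 40), 50, 40)
#' fit <- ipca_fit(x, ncomp = 2, seed = 1)
#' fit$kurtosis
#' @export
ipca_fit <- function(data, ncomp = 2, contrast = c("logcosh", "pow3"),
                     tol = 1e-6, max_iter = 1000, n_restarts = 1,
                     seed = NULL, sample_col = NULL) {
  contrast <- match.arg(contrast)
  ci <- center_info(data, sample_col = sample_col)
  core <- ipca_core(ci$xc, ncomp = ncomp, contrast = contrast, tol = tol,
                    max_iter = max_iter, n_restarts = n_restarts, seed = seed)
  dress_ipca(core, ci, keepX = NULL)
}

#' Sparse independent principal component analysis
#'
#' Runs [ipca_fit()], then soft-thresholds each kurtosis-ordered independent
#' loading vector so that exactly `keepX[j]` variables keep non-zero weight
#' on component j, and recomputes the scores by projecting the centered data
#' onto the sparse loadings — noisy variables are removed from the
#' components themselves, not just from the report. Thresholds are induced
#' from `keepX` by order statistics, so the selection is exact and gene
#' lists for decreasing `keepX` are nested.
#'
#' @inheritParams ipca_fit
#' @param keepX number of variables to retain per component; a single value
#'   is broadcast to all components.
#' @return an `ipca_fit` object (additionally of class `sipca_fit`) whose
#'   `loadings` are sparse; `keepX`, `gamma` (induced thresholds) and
#'   `selected` (list of retained variable indices per component) describe
#'   the sparsity plan, and `dense_loadings` keeps the unthresholded
#'   loadings.
#' @examples
#' x <- matrix(rnorm(50 * 40), 50, 40)
#' fit <- sipca_fit(x, ncomp = 2, keepX = 10, seed = 1)
#' colSums(fit$loadings != 0)
#' @export
sipca_fit <- function(data, ncomp = 2, keepX = 50,
                      contrast = c("logcosh", "pow3"), tol = 1e-6,
                      max_iter = 1000, n_restarts = 1, seed = NULL,
                      sample_col = NULL) {
  contrast <- match.arg(contrast)
  ci <- center_info(data, sample_col = sample_col)
  ncomp_chk <- check_count(ncomp, "ncomp", min = 2L,
                           max = min(nrow(ci$xc), ncol(ci$xc)))
  if (length(keepX) == 1L) keepX <- rep(keepX, ncomp_chk)
  if (length(keepX) != ncomp_chk) {
    abort("`keepX` must have length 1 or `ncomp`.")
  }
  keepX <- vapply(seq_along(keepX), function(j) {
    check_count(keepX[j], sprintf("keepX[%d]", j), min = 1L, max = ncol(ci$xc))
  }, integer(1))
  core <- ipca_core(ci$xc, ncomp = ncomp_chk, contrast = contrast, tol = tol,
                    max_iter = max_iter, n_restarts = n_restarts, seed = seed)
  dress_ipca(core, ci, keepX = keepX)
}

## shared math: centered matrix -> ordered independent loadings + scores.
## `sv` lets callers that already decomposed xc (the replicate runner) skip
## the SVD.
ipca_core <- function(xc, ncomp, contrast = "logcosh", tol = 1e-6,
                      max_iter = 1000, n_restarts = 1, seed = NULL,
                      sv = NULL) {
  n <- nrow(xc); p <- ncol(xc)
  ncomp <- check_count(ncomp, "ncomp", min = 2L, max = min(n, p))
  if (is.null(sv)) sv <- svd(xc, nu = 0, nv = ncomp)
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  ## loading columns are unit-norm; standardize to zero mean, unit
  ## population variance before treating them as signals
  vs <- apply(v, 2, standardize_pop)
  fi <- fast_ica(t(vs), contrast = contrast, tol = tol, max_iter = max_iter,
                 seed = seed, n_restarts = n_restarts)
  kur <- apply(fi$S, 1, kurtosis_excess)
  ord <- order(kur, decreasing = TRUE)
  loadings <- t(fi$S[ord, , drop = FALSE])   # p x m, columns ordered
  loadings <- fix_signs(loadings)
  scores <- xc %*% loadings
  list(loadings = loadings, scores = scores, kurtosis = kur[ord],
       order = ord, converged = fi$converged,
       n_iterations = fi$n_iterations, contrast = contrast, seed = seed)
}

## attach names/class and (optionally) the sparsity plan
dress_ipca <- function(core, ci, keepX = NULL) {
  m <- ncol(core$loadings)
  comp <- paste0("IPC", seq_len(m))
  out <- core
  dimnames(out$loadings) <- list(ci$variable_names, comp)
  dimnames(out$scores) <- list(ci$sample_ids, comp)
  out$center <- ci$means
  out$sample_ids <- ci$sample_ids
  out$variable_names <- ci$variable_names
  out$ncomp <- m
  cls <- "ipca_fit"
  if (!is.null(keepX)) {
    dense <- out$loadings
    sparse <- matrix(0, nrow(dense), m, dimnames = dimnames(dense))
    gamma <- numeric(m)
    selected <- vector("list", m)
    for (j in seq_len(m)) {
      sp <- sparsify_exact(dense[, j], keepX[j])
      sparse[, j] <- sp$values
      gamma[j] <- sp$gamma
      selected[[j]] <- sp$keep
    }
    out$dense_loadings <- dense
    out$loadings <- sparse
    out$scores <- ci$xc %*% sparse
    dimnames(out$scores) <- list(ci$sample_ids, comp)
    out$keepX <- keepX
    out$gamma <- gamma
    out$selected <- selected
    cls <- c("sipca_fit", cls)
  }
  structure(out, class = cls)
}

#' Kurtosis drop report
#'
#' Lists each component's loading-vector excess kurtosis together with the
#' drop from the previous component. A sudden drop marks the transition
#' from structured (super-Gaussian) loading vectors to noise, and is the
#' recommended post-hoc guide for choosing how many components to keep. The
#' report is descriptive; no automatic cutoff is applied.
#'
#' @param fit an [ipca_fit()] (or [sipca_fit()]) object.
#' @return a tibble with `component`, `kurtosis` and `drop` (kurtosis of
#'   the previous component minus this one; 0 for the first).
#' @examples
#' x <- matrix(rnorm(50 * 40), 50, 40)
#' kurtosis_drop(ipca_fit(x, ncomp = 3, seed = 1))
#' @export
kurtosis_drop <- function(fit) {
  stopifnot(inherits(fit, "ipca_fit"))
  k <- fit$kurtosis
  tibble::tibble(
    component = seq_along(k),
    kurtosis = k,
    drop = c(0, -diff(k))
  )
}

#' @export
print.ipca_fit <- function(x, ...) {
  cat(sprintf("IPCA fit: %d samples x %d variables, %d component(s)\n",
              length(x$sample_ids), length(x$variable_names), x$ncomp))
  cat("loading kurtosis:", paste0(sprintf("%.2f", x$kurtosis), collapse = " "),
      "\n")
  if (!is.null(x$keepX)) {
    cat("keepX:", paste0(x$keepX, collapse = " "), "\n")
  }
  if (!x$converged) cat("note: FastICA did not converge\n")
  invisible(x)
}
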