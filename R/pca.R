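#' Principal component analysis by singular value decomposition
#'
#' Centers the data and factors it as \eqn{X = U D V^\top}: the columns of
#' `V` are the loading vectors, `U D` holds the principal components
#' (scores), and the squared singular values give the variance explained by
#' each component. Signs are fixed so that each loading column's entry of
#' largest absolute value is positive, making results reproducible across
#' runs and platforms.
#'
#' @param data a samples-by-variables matrix or data frame
#'   (see [as_data_matrix()]).
#' @param ncomp number of components to retain, between 1 and `min(n, p)`.
#' @inheritParams as_data_matrix
#' @return an object of class `pca_fit`: a list with `loadings` (p x ncomp),
#'   `scores` (n x ncomp, equal to `U %*% diag(D)`), `d` (singular values of
#'   the full decomposition), `explained_variance` (fractions summing to 1
#'   over all `min(n,p)` components), `center` (column means) and naming
#'   metadata.
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' fit <- pca_fit(x, ncomp = 2)
#' fit$explained_variance[1:2]
#' @export
pca_fit <- function(data, ncomp = 2, sample_col = NULL) {
  ci <- center_info(data, sample_col = sample_col)
  xc <- ci$xc
  n <- nrow(xc); p <- ncol(xc)
  r <- min(n, p)
  ncomp <- check_count(ncomp, "ncomp", min = 1L, max = r)
  if (all(abs(xc) < .Machine$double.eps * 100)) {
    abort("matrix has zero variance; nothing to decompose.")
  }
  zero_var <- apply(xc, 2, function(col) all(col == 0))
  if (any(zero_var)) {
    abort(sprintf("zero-variance variable(s): %s",
                  paste(ci$variable_names[zero_var], collapse = ", ")))
  }
  sv <- svd(xc)
  sgn <- apply(sv$v, 2, function(x) {
    s <- sign(x[which.max(abs(x))]); if (s == 0) 1 else s
  })
  v <- sweep(sv$v, 2, sgn, `*`)
  u <- sweep(sv$u, 2, sgn, `*`)
  expl <- sv$d^2 / sum(sv$d^2)
  loadings <- v[, seq_len(ncomp), drop = FALSE]
  scores <- u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  dimnames(loadings) <- list(ci$variable_names, paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(ci$sample_ids, paste0("PC", seq_len(ncomp)))
  structure(
    list(loadings = loadings, scores = scores,
         u = u[, seq_len(ncomp), drop = FALSE],
         d = sv$d, ncomp = ncomp,
         explained_variance = expl,
         center = ci$means,
         sample_ids = ci$sample_ids, variable_names = ci$variable_names),
    class = "pca_fit")
}

#' Whitened principal component scores
#'
#' Rescales the left singular vectors so that each retained component has
#' zero mean and unit sample variance and components are mutually
#' uncorrelated — the preprocessing FastICA expects. Scaling by
#' \eqn{\sqrt{n-1}} achieves unit sample variance because each column of
#' `U` has zero mean and unit norm for a centered matrix.
#'
#' @param pca a [pca_fit()] object.
#' @param ncomp how many leading components to whiten
#'   (default: all retained).
#' @return an n x ncomp matrix of whitened component scores.
#' @examples
#' fit <- pca_fit(matrix(rnorm(200), 20, 10), ncomp = 3)
#' w <- whiten_scores(fit)
#' round(crossprod(w) / (nrow(w) - 1), 8)  # identity
#' @export
whiten_scores <- function(pca, ncomp = pca$ncomp) {
  stopifnot(inherits(pca, "pca_fit"))
  ncomp <- check_count(ncomp, "ncomp", min = 1L, max = pca$ncomp)
  d <- pca$d[seq_len(ncomp)]
  if (any(d <= .Machine$double.eps * max(pca$d) * max(dim(pca$u)))) {
    abort("zero singular value among retained components; cannot whiten.")
  }
  n <- nrow(pca$u)
  w <- pca$u[, seq_len(ncomp), drop = FALSE] * sqrt(n - 1)
  dimnames(w) <- list(pca$sample_ids, paste0("PC", seq_len(ncomp)))
  w
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("PCA fit: %d samples x %d variables, %d component(s)\n",
              length(x$sample_ids), length(x$variable_names), x$ncomp))
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance[seq_len(x$ncomp)]),
             collapse = " "), "\n")
  invisible(x)
}
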