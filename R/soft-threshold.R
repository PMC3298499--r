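#' Soft-threshold a loading vector
#'
#' The elementwise shrinkage operator
#' \eqn{\hat s_k = \mathrm{sign}(s_k)(|s_k| - \gamma)_+}: entries with
#' absolute value at most `gamma` become exactly zero, the rest shrink
#' toward zero by `gamma`. This is the operator behind most sparse-PCA
#' variants and the one sparse IPCA applies directly to independent loading
#' vectors.
#'
#' @param loading numeric vector.
#' @param gamma non-negative threshold.
#' @return the thresholded vector; its support is `{k : |s_k| > gamma}`.
#' @examples
#' soft_threshold(c(0.5, -0.2, 0.1), 0.15)  # 0.35 -0.05 0.00
#' @export
soft_threshold <- function(loading, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    abort("`gamma` must be a single non-negative number.")
  }
  sign(loading) * pmax(abs(loading) - gamma, 0)
}

#' Threshold inducing a requested degree of sparsity
#'
#' Users choose sparsity as the number of variables to keep per component
#' (`keepX`) rather than as a raw threshold. The induced threshold is the
#' (`keepX` + 1)-th largest absolute loading value (0 when `keepX` equals
#' the vector length), so that [soft_threshold()] retains exactly `keepX`
#' non-zero entries. Ties in absolute value are broken by keeping the lower
#' variable index first.
#'
#' @param loading numeric vector.
#' @param keepX number of entries to retain, between 1 and `length(loading)`.
#' @return a list with `gamma` (the induced threshold) and `keep` (the
#'   integer indices retained under the tie rule).
#' @examples
#' keepx_to_gamma(c(3, 1, 2), 2)$gamma  # 1
#' @export
keepx_to_gamma <- function(loading, keepX) {
  p <- length(loading)
  keepX <- check_count(keepX, "keepX", min = 1L, max = p)
  if (keepX == p) {
    return(list(gamma = 0, keep = seq_len(p)))
  }
  a <- abs(loading)
  ord <- order(-a, seq_len(p))      # abs descending, ties by lower index
  keep <- sort(ord[seq_len(keepX)])
  gamma <- max(a[ord[(keepX + 1L):p]])
  list(gamma = gamma, keep = keep)
}

## exact-count sparsification: zero everything outside the kept set, shrink
## the kept entries by the induced threshold
sparsify_exact <- function(loading, keepX) {
  kg <- keepx_to_gamma(loading, keepX)
  out <- numeric(length(loading))
  out[kg$keep] <- sign(loading[kg$keep]) * pmax(abs(loading[kg$keep]) - kg$gamma, 0)
  list(values = out, gamma = kg$gamma, keep = kg$keep)
}
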