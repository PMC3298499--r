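#' Classical independent component analysis of samples
#'
#' The standard ICA pipeline for expression matrices: PCA whitening of the
#' sample scores followed by FastICA. The leading `n_whiten` principal
#' components are rescaled to unit variance ([whiten_scores()]) and FastICA
#' recovers `ncomp` independent components (ICs) in sample space; ICs are
#' ordered by their own excess kurtosis, largest first. For comparison with
#' loading-based methods, each IC is also mapped back to variable space:
#' since IC\eqn{_j = X \, V_m D_m^{-1} w_j^\top \sqrt{n-1}}, the direction
#' in variable space whose projection generates IC j is the unit-normalized
#' \eqn{V_m D_m^{-1} w_j^\top}; these are returned as `loadings`.
#'
#' @inheritParams ipca_fit
#' @param n_whiten how many principal components to whiten before unmixing
#'   (default: `ncomp`).
#' @return an object of class `ica_fit`: `scores` (n x ncomp ICs,
#'   kurtosis-ordered), `loadings` (p x ncomp unit-norm variable-space
#'   directions in the same order), `kurtosis` (of the ICs),
#'   `loading_kurtosis`, `mixing` (n x ncomp, `scores`-to-data map),
#'   `order`, diagnostics and metadata.
#' @examples
#' x <- matrix(rnorm(50 * 30), 50, 30)
#' fit <- ica_fit(x, ncomp = 2, seed = 1)
#' round(crossprod(scale(fit$scores, scale = FALSE)) / (50 - 1), 6)
#' @export
ica_fit <- function(data, ncomp = 2, n_whiten = ncomp,
                    contrast = c("logcosh", "pow3"), tol = 1e-6,
                    max_iter = 1000, n_restarts = 1, seed = NULL,
                    sample_col = NULL) {
  contrast <- match.arg(contrast)
  ci <- center_info(data, sample_col = sample_col)
  core <- ica_core(ci$xc, ncomp = ncomp, n_whiten = n_whiten,
                   contrast = contrast, tol = tol, max_iter = max_iter,
                   n_restarts = n_restarts, seed = seed)
  comp <- paste0("IC", seq_len(core$ncomp))
  dimnames(core$scores) <- list(ci$sample_ids, comp)
  dimnames(core$loadings) <- list(ci$variable_names, comp)
  core$center <- ci$means
  core$sample_ids <- ci$sample_ids
  core$variable_names <- ci$variable_names
  structure(core, class = "ica_fit")
}

ica_core <- function(xc, ncomp, n_whiten = ncomp, contrast = "logcosh",
                     tol = 1e-6, max_iter = 1000, n_restarts = 1,
                     seed = NULL, sv = NULL) {
  n <- nrow(xc); p <- ncol(xc)
  ncomp <- check_count(ncomp, "ncomp", min = 2L, max = min(n, p))
  n_whiten <- check_count(n_whiten, "n_whiten", min = ncomp, max = min(n, p))
  if (is.null(sv)) sv <- svd(xc, nu = n_whiten, nv = n_whiten)
  d <- sv$d[seq_len(n_whiten)]
  if (any(d <= 1e-12 * sv$d[1])) {
    abort("zero singular value among whitening components.")
  }
  uw <- sv$u[, seq_len(n_whiten), drop = FALSE] * sqrt(n - 1)
  fi <- fast_ica(t(uw), contrast = contrast, tol = tol, max_iter = max_iter,
                 seed = seed, n_restarts = n_restarts)
  kur <- apply(fi$S, 1, kurtosis_excess)
  ord <- order(kur, decreasing = TRUE)[seq_len(ncomp)]
  ## total unmixing applied to the whitened scores, including the engine's
  ## internal whitening transform
  w <- (fi$W %*% fi$K)[ord, , drop = FALSE]
  scores <- t(fi$S[ord, , drop = FALSE])           # n x ncomp ICs
  ## variable-space direction generating IC j: V_m D_m^{-1} w_j
  vm <- sv$v[, seq_len(n_whiten), drop = FALSE]
  loadings <- vm %*% (t(w) / d)
  loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), `/`)
  loadings <- fix_signs(loadings)
  mixing <- uw %*% t(w) / (n - 1)                  # scores-to-data map
  list(scores = scores, loadings = loadings,
       kurtosis = kur[ord],
       loading_kurtosis = apply(loadings, 2, kurtosis_excess),
       mixing = mixing, order = ord, ncomp = ncomp, n_whiten = n_whiten,
       converged = fi$converged, n_iterations = fi$n_iterations,
       contrast = contrast, seed = seed)
}

#' Sparse principal component analysis by regularized rank-1 SVD
#'
#' Sequential sparse rank-1 extraction with soft-thresholding: for each
#' component, alternate a score update `u = X v / ||X v||` with a loading
#' update `v = soft_threshold(X'u, gamma)` where `gamma` is refreshed each
#' iteration from `keepX` by order statistics (exact-count sparsity), until
#' the loading direction stabilizes; then deflate by projecting out the
#' component's score direction, `X <- X - u (u'X)`. Columns are by default
#' standardized to unit variance before extraction, the convention of the
#' reference implementations of this method family.
#'
#' @inheritParams sipca_fit
#' @param ncomp number of components (>= 1).
#' @param scale standardize columns to unit variance first? (default TRUE)
#' @param tol convergence tolerance on the relative change of the loading
#'   vector between iterations.
#' @param max_iter maximum alternations per component.
#' @return an object of class `spca_fit`: `loadings` (p x ncomp, each
#'   column has exactly `keepX[j]` non-zeros and unit Euclidean norm),
#'   `scores` (n x ncomp, scores of each component on its deflated matrix),
#'   `keepX`, `gamma`, `selected`, `iterations`, `converged`, metadata.
#' @examples
#' x <- matrix(rnorm(30 * 20), 30, 20)
#' fit <- spca_fit(x, ncomp = 2, keepX = 5)
#' colSums(fit$loadings != 0)
#' @export
spca_fit <- function(data, ncomp = 2, keepX = 50, scale = TRUE, tol = 1e-6,
                     max_iter = 500, sample_col = NULL) {
  ci <- center_info(data, sample_col = sample_col)
  ncomp <- check_count(ncomp, "ncomp", min = 1L,
                       max = min(nrow(ci$xc), ncol(ci$xc)))
  if (length(keepX) == 1L) keepX <- rep(keepX, ncomp)
  if (length(keepX) != ncomp) abort("`keepX` must have length 1 or `ncomp`.")
  keepX <- vapply(seq_along(keepX), function(j) {
    check_count(keepX[j], sprintf("keepX[%d]", j), min = 1L, max = ncol(ci$xc))
  }, integer(1))
  core <- spca_core(ci$xc, ncomp = ncomp, keepX = keepX, scale = scale,
                    tol = tol, max_iter = max_iter)
  comp <- paste0("sPC", seq_len(ncomp))
  dimnames(core$loadings) <- list(ci$variable_names, comp)
  dimnames(core$scores) <- list(ci$sample_ids, comp)
  core$center <- ci$means
  core$sample_ids <- ci$sample_ids
  core$variable_names <- ci$variable_names
  structure(core, class = "spca_fit")
}

spca_core <- function(xc, ncomp, keepX, scale = TRUE, tol = 1e-6,
                      max_iter = 500) {
  x <- xc
  if (scale) {
    sds <- sqrt(colSums(x^2) / (nrow(x) - 1))
    if (any(sds == 0)) abort("cannot rescale a zero-variance variable.")
    x <- sweep(x, 2, sds, `/`)
  }
  n <- nrow(x); p <- ncol(x)
  loadings <- matrix(0, p, ncomp)
  scores <- matrix(0, n, ncomp)
  gamma <- numeric(ncomp)
  selected <- vector("list", ncomp)
  iters <- integer(ncomp)
  converged <- logical(ncomp)
  for (j in seq_len(ncomp)) {
    sv <- svd(x, nu = 0, nv = 1)
    v <- sv$d[1] * sv$v[, 1]
    it <- 0L
    repeat {
      it <- it + 1L
      u <- drop(x %*% v)
      u <- u / sqrt(sum(u^2))
      sp <- sparsify_exact(drop(crossprod(x, u)), keepX[j])
      vn <- sp$values
      if (all(vn == 0)) {
        warn(sprintf("sparse PCA component %d collapsed to zero under ties.", j))
        vn <- sp$values <- replace(vn, sp$keep[1], 1)
      }
      dv <- sum((vn / sqrt(sum(vn^2)) - v / sqrt(sum(v^2)))^2)
      dv2 <- sum((vn / sqrt(sum(vn^2)) + v / sqrt(sum(v^2)))^2)
      v <- vn
      if (min(dv, dv2) < tol) { converged[j] <- TRUE; break }
      if (it >= max_iter) {
        warn(sprintf("sparse PCA component %d did not converge in %d iterations.",
                     j, max_iter))
        break
      }
    }
    iters[j] <- it
    gamma[j] <- sp$gamma
    selected[[j]] <- sp$keep
    u <- drop(x %*% v)
    scores[, j] <- u
    vnorm <- v / sqrt(sum(v^2))
    loadings[, j] <- vnorm
    uu <- u / sqrt(sum(u^2))
    x <- x - uu %*% crossprod(uu, x)   # projection deflation
  }
  sgn <- apply(loadings, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  loadings <- sweep(loadings, 2, sgn, `*`)
  scores <- sweep(scores, 2, sgn, `*`)
  list(loadings = loadings, scores = scores, keepX = keepX, gamma = gamma,
       selected = selected, iterations = iters, converged = converged,
       scale = scale)
}

#' @export
print.ica_fit <- function(x, ...) {
  cat(sprintf("ICA fit: %d component(s), whitened on %d PCs\n",
              x$ncomp, x$n_whiten))
  cat("IC kurtosis:", paste0(sprintf("%.2f", x$kurtosis), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.spca_fit <- function(x, ...) {
  cat(sprintf("sparse PCA fit: %d component(s), keepX = %s\n",
              length(x$keepX), paste0(x$keepX, collapse = " ")))
  invisible(x)
}
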