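#' Fixed-point FastICA with symmetric decorrelation
#'
#' Recovers maximally non-Gaussian, statistically independent source signals
#' from a small set of (approximately) whitened mixtures. Each row of
#' `signals` is one mixture; the algorithm exactly whitens the rows
#' internally (population moments), then iterates the fixed-point update
#' under the chosen contrast with symmetric (parallel) decorrelation, so the
#' unmixing matrix stays orthogonal at every iteration and no component is
#' privileged by extraction order.
#'
#' Non-Gaussianity is measured through a contrast function standing in for
#' negentropy: `logcosh` (robust, the default) or `pow3` (kurtosis-based).
#' Convergence is declared when no component's direction changes by more
#' than `tol` between iterations (via `max |diag(W_new W_old')| - 1`).
#' Non-convergence raises a warning, not an error: with Gaussian inputs the
#' model is unidentifiable and the algorithm may legitimately wander.
#'
#' @param signals an m x q matrix, one signal per row, q > m >= 2.
#' @param contrast `"logcosh"` or `"pow3"`.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter maximum number of fixed-point iterations.
#' @param seed integer seed for the random orthogonal initialisation of the
#'   unmixing matrix; `NULL` uses the current RNG stream.
#' @param n_restarts number of seeded restarts; with more than one, runs are
#'   aligned by absolute correlation and the run with the lowest mean
#'   absolute pairwise source correlation is returned (ties broken by the
#'   lowest seed).
#' @return an object of class `fast_ica`: `W` (m x m orthogonal rotation of
#'   the whitened signals), `K` (the m x m internal whitening transform),
#'   `S` (m x q recovered sources, rows zero-mean unit-variance and
#'   mutually uncorrelated), `n_iterations`, `converged`, `seed`.
#' @examples
#' set.seed(1)
#' s <- rbind(sign(rnorm(500)) * rexp(500), sign(rnorm(500)) * rexp(500))
#' a <- matrix(c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2)
#' fit <- fast_ica(a %*% s, seed = 7)
#' round(abs(cor(t(fit$S), t(s))), 2)  # near-permutation
#' @export
fast_ica <- function(signals, contrast = c("logcosh", "pow3"), tol = 1e-6,
                     max_iter = 1000, seed = NULL, n_restarts = 1) {
  contrast <- match.arg(contrast)
  n_restarts <- check_count(n_restarts, "n_restarts", min = 1L)
  if (n_restarts == 1L) {
    return(fastica_single(signals, contrast, tol, max_iter, seed))
  }
  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n_restarts)
  } else {
    as.integer(seed) + seq_len(n_restarts) - 1L
  }
  runs <- lapply(seeds, function(s) {
    fastica_single(signals, contrast, tol, max_iter, s)
  })
  ## align every run onto the first by greedy absolute-correlation matching
  ref <- runs[[1L]]
  runs <- lapply(runs, align_sources, ref = ref)
  score <- vapply(runs, function(r) {
    cc <- abs(cor(t(r$S)))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  ## ties broken by lowest seed: seeds are in increasing order, which.min
  ## returns the first minimum
  best <- which.min(round(score, 12))
  out <- runs[[best]]
  out$restart_scores <- score
  out
}

fastica_single <- function(signals, contrast, tol, max_iter, seed) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    abort("`signals` must be a numeric matrix with one signal per row.")
  }
  m <- nrow(signals); q <- ncol(signals)
  if (m < 2L) abort("need at least 2 signals.")
  if (q <= m) abort("signals must be longer than their number (q > m).")
  if (any(!is.finite(signals))) abort("non-finite values in `signals`.")
  tol <- as.numeric(tol)
  max_iter <- check_count(max_iter, "max_iter", min = 1L)

  x <- signals - rowMeans(signals)
  cc <- tcrossprod(x) / q
  ev <- eigen(cc, symmetric = TRUE)
  if (ev$values[m] <= 1e-12 * max(ev$values[1], .Machine$double.eps)) {
    abort("rank-deficient input: signals are linearly dependent.")
  }
  k <- diag(1 / sqrt(ev$values), m) %*% t(ev$vectors)
  z <- k %*% x                       # exactly whitened rows

  w <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(m * m), m, m)))
  })
  w <- sym_decorrelate(w)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wz <- w %*% z
    if (contrast == "logcosh") {
      g <- tanh(wz)
      gprime_mean <- rowMeans(1 - g^2)
    } else {
      g <- wz^3
      gprime_mean <- rowMeans(3 * wz^2)
    }
    w_new <- tcrossprod(g, z) / q - diag(gprime_mean, m) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(tcrossprod(w_new, w))) - 1))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("FastICA did not converge in %d iterations (last change %.2e).",
                 max_iter, delta))
  }
  s <- w %*% z
  structure(
    list(W = w, K = k, S = s, n_iterations = it, converged = converged,
         contrast = contrast, seed = seed),
    class = "fast_ica")
}

## symmetric (parallel) decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(w)) %*% t(e$vectors) %*% w
}

## permute and sign-flip the components of `run` to best match `ref`
align_sources <- function(run, ref) {
  m <- nrow(run$S)
  cc <- cor(t(ref$S), t(run$S))
  perm <- integer(m)
  taken <- rep(FALSE, m)
  for (i in seq_len(m)) {
    j <- which.max(ifelse(taken, -Inf, abs(cc[i, ])))
    perm[i] <- j
    taken[j] <- TRUE
  }
  sgn <- sign(cc[cbind(seq_len(m), perm)])
  sgn[sgn == 0] <- 1
  run$S <- run$S[perm, , drop = FALSE] * sgn
  run$W <- run$W[perm, , drop = FALSE] * sgn
  run
}

#' @export
print.fast_ica <- function(x, ...) {
  cat(sprintf("FastICA (%s): %d sources, %d iterations, %s\n",
              x$contrast, nrow(x$S), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
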