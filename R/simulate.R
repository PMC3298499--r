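#' Design of a planted-eigenvector simulation
#'
#' The benchmark generator plants two known leading eigenvectors into a
#' covariance matrix and samples multivariate-normal data from it:
#' \eqn{\Sigma = V C V^\top} where the first two columns of the orthogonal
#' matrix `V` are the planted unit vectors `v1`, `v2` with eigenvalues
#' `c1`, `c2`, and all remaining eigenvalues equal `c_rest`. Four regimes
#' for the planted vectors are supported:
#'
#' * `"gaussian"` — i.i.d. standard-normal entries;
#' * `"super_gaussian"` — Laplace(0, `laplace_scale`) entries on a
#'   50-variable support (indices 1-50 for `v1`, 301-350 for `v2` at the
#'   default p = 500), U(0, 1) elsewhere;
#' * `"sparse_gaussian"` — standard-normal on the support, exactly zero
#'   elsewhere;
#' * `"sparse_super_gaussian"` — Laplace on the support, zero elsewhere.
#'
#' Defaults (n = 50, p = 500, c1 = 400, c2 = 300, c_rest = 1) are the
#' standard benchmark conditions for this generator.
#'
#' @param case one of `"gaussian"`, `"super_gaussian"`, `"sparse_gaussian"`,
#'   `"sparse_super_gaussian"`.
#' @param n,p samples and variables per dataset.
#' @param c1,c2 the two planted eigenvalues (`c1 >= c2 > c_rest`).
#' @param c_rest the common trailing eigenvalue.
#' @param laplace_scale scale parameter b of the Laplace distribution used
#'   for super-Gaussian supports (location 0).
#' @return an object of class `sim_design` (a validated list) including the
#'   two support index sets used by the sparse and super-Gaussian cases.
#' @examples
#' sim_design("super_gaussian")
#' @export
sim_design <- function(case = c("gaussian", "super_gaussian",
                                "sparse_gaussian", "sparse_super_gaussian"),
                       n = 50, p = 500, c1 = 400, c2 = 300, c_rest = 1,
                       laplace_scale = 25) {
  case <- match.arg(case)
  n <- check_count(n, "n", min = 4L)
  p <- check_count(p, "p", min = 4L)
  if (!is.numeric(c1) || !is.numeric(c2) || !is.numeric(c_rest) ||
      !(c1 >= c2 && c2 > c_rest && c_rest > 0)) {
    abort("need c1 >= c2 > c_rest > 0.")
  }
  if (!is.numeric(laplace_scale) || laplace_scale <= 0) {
    abort("`laplace_scale` must be positive.")
  }
  ## support layout: 1..k and (0.6 p)+1 .. (0.6 p)+k, the printed layout
  ## 1-50 / 301-350 at the default p = 500
  k <- max(2L, min(50L, floor(p / 10)))
  s2_start <- floor(0.6 * p)
  if (s2_start + k > p) s2_start <- p - k
  structure(
    list(case = case, n = n, p = p, c1 = c1, c2 = c2, c_rest = c_rest,
         laplace_scale = laplace_scale,
         support1 = seq_len(k), support2 = s2_start + seq_len(k)),
    class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("simulation design: %s, n = %d, p = %d, eigenvalues (%g, %g, %g...)\n",
              x$case, x$n, x$p, x$c1, x$c2, x$c_rest))
  invisible(x)
}

## Laplace(0, b) sampler by inverse CDF
rlaplace <- function(n, b) {
  u <- runif(n, -0.5, 0.5)
  -b * sign(u) * log(1 - 2 * abs(u))
}

## draw the two planted eigenvectors for a design (un-normalized)
draw_planted <- function(design) {
  p <- design$p
  b <- design$laplace_scale
  s1 <- design$support1; s2 <- design$support2
  switch(design$case,
    gaussian = list(v1 = rnorm(p), v2 = rnorm(p)),
    super_gaussian = {
      v1 <- runif(p); v1[s1] <- rlaplace(length(s1), b)
      v2 <- runif(p); v2[s2] <- rlaplace(length(s2), b)
      list(v1 = v1, v2 = v2)
    },
    sparse_gaussian = {
      v1 <- numeric(p); v1[s1] <- rnorm(length(s1))
      v2 <- numeric(p); v2[s2] <- rnorm(length(s2))
      list(v1 = v1, v2 = v2)
    },
    sparse_super_gaussian = {
      v1 <- numeric(p); v1[s1] <- rlaplace(length(s1), b)
      v2 <- numeric(p); v2[s2] <- rlaplace(length(s2), b)
      list(v1 = v1, v2 = v2)
    })
}

## orthonormalize the pair (v1 first, then v2 against v1)
orthonormalize_pair <- function(v1, v2) {
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 - sum(v2 * v1) * v1
  nv2 <- sqrt(sum(v2^2))
  if (nv2 < 1e-12) abort("planted eigenvectors are collinear.")
  list(v1 = v1, v2 = v2 / nv2)
}

#' Build the full planted covariance matrix
#'
#' Constructs the orthogonal matrix `V` (planted `v1`, `v2` first, the
#' remaining columns drawn with U(0, 1) entries and orthonormalized via
#' Householder QR with signs fixed so the leading columns keep the planted
#' directions) and assembles \eqn{\Sigma = V C V^\top}. Because the
#' trailing eigenvalues all equal `c_rest`, \eqn{\Sigma} also equals
#' \eqn{c_{rest} I + (c_1 - c_{rest}) v_1 v_1^\top +
#' (c_2 - c_{rest}) v_2 v_2^\top} exactly — the identity [sim_dataset()]
#' exploits to sample without forming \eqn{\Sigma}. This constructor is for
#' inspection and testing at moderate p (it is O(p^3)).
#'
#' @param design a [sim_design()] object.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param max_retries how many times to redraw if the random matrix is
#'   numerically rank-deficient.
#' @return a list with `sigma` (p x p), `V` (p x p orthogonal), `eigenvalues`
#'   (the diagonal of C), `true_v1`, `true_v2` (the orthonormalized planted
#'   vectors) and the sparse supports.
#' @examples
#' cv <- build_covariance(sim_design("gaussian", p = 50), seed = 1)
#' range(eigen(cv$sigma, symmetric = TRUE, only.values = TRUE)$values[3:50])
#' @export
build_covariance <- function(design, seed = NULL, max_retries = 5) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(seed, {
    p <- design$p
    for (try in seq_len(max_retries)) {
      pl <- draw_planted(design)
      pair <- orthonormalize_pair(pl$v1, pl$v2)
      a <- cbind(pair$v1, pair$v2,
                 matrix(runif(p * (p - 2L)), p, p - 2L))
      qr_a <- qr(a)
      if (qr_a$rank == p) break
      if (try == max_retries) {
        abort("could not draw a full-rank eigenvector matrix.")
      }
      warn("rank-deficient eigenvector draw; resampling.")
    }
    v <- qr.Q(qr_a)
    sgn <- sign(diag(qr.R(qr_a)))
    sgn[sgn == 0] <- 1
    v <- sweep(v, 2, sgn, `*`)
    eigenvalues <- c(design$c1, design$c2, rep(design$c_rest, p - 2L))
    sigma <- v %*% (t(v) * eigenvalues)
    sigma <- (sigma + t(sigma)) / 2
    list(sigma = sigma, V = v, eigenvalues = eigenvalues,
         true_v1 = v[, 1], true_v2 = v[, 2],
         support1 = design$support1, support2 = design$support2)
  })
}

#' Sample one dataset from a planted-eigenvector design
#'
#' Draws the planted eigenvectors, orthonormalizes them, and samples `n`
#' rows from \eqn{N(0, \Sigma)} using the exact rank-2 representation
#' \eqn{\Sigma^{1/2} = \sqrt{c_{rest}}\, I + (\sqrt{c_1} - \sqrt{c_{rest}})
#' v_1 v_1^\top + (\sqrt{c_2} - \sqrt{c_{rest}}) v_2 v_2^\top}
#' (valid because all trailing eigenvalues are equal), which is O(np) per
#' dataset. Deterministic given `seed`.
#'
#' @inheritParams build_covariance
#' @return an object of class `sim_dataset`: `data` (n x p matrix with
#'   sample and variable names), `true_v1`, `true_v2` (orthonormal),
#'   `support1`, `support2` (index sets, meaningful for the sparse and
#'   super-Gaussian cases), and the `design`.
#' @examples
#' d <- sim_dataset(sim_design("sparse_gaussian", p = 100), seed = 1)
#' sum(d$true_v1 != 0)
#' @export
sim_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(seed, {
    pl <- draw_planted(design)
    pair <- orthonormalize_pair(pl$v1, pl$v2)
    x <- sample_mvn_rank2(design, pair$v1, pair$v2)
    dimnames(x) <- list(paste0("sample_", seq_len(design$n)),
                        paste0("V", seq_len(design$p)))
    structure(
      list(data = x, true_v1 = pair$v1, true_v2 = pair$v2,
           support1 = design$support1, support2 = design$support2,
           design = design),
      class = "sim_dataset")
  })
}

sample_mvn_rank2 <- function(design, v1, v2) {
  n <- design$n; p <- design$p
  sr <- sqrt(design$c_rest)
  z <- matrix(rnorm(n * p), n, p) * sr
  z + ((sqrt(design$c1) - sr) / sr) * (z %*% v1) %*% t(v1) +
    ((sqrt(design$c2) - sr) / sr) * (z %*% v2) %*% t(v2)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset: %s, %d x %d\n", x$design$case,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
as.data.frame.sim_dataset <- function(x, ...) {
  as.data.frame(x$data)
}
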