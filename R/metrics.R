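#' Excess kurtosis of a signal
#'
#' Standardizes `x` to zero mean and unit variance using population
#' (divisor-q) moments and returns the fourth moment minus 3: zero for a
#' Gaussian signal, positive for spiky (super-Gaussian) densities such as
#' the Laplace (+3), negative for flat (sub-Gaussian) densities such as the
#' uniform (-1.2). Used both to order components by the non-Gaussianity of
#' their loading vectors and as a reported diagnostic. No small-sample
#' correction is applied, so ordering and reporting use the same estimator.
#'
#' @param x numeric vector, length >= 4, non-constant.
#' @return excess kurtosis (a single number).
#' @examples
#' kurtosis_excess(runif(1e5))  # about -1.2
#' @export
kurtosis_excess <- function(x) {
  if (!is.numeric(x) || length(x) < 4L) {
    abort("`x` must be a numeric vector of length >= 4.")
  }
  if (any(!is.finite(x))) abort("non-finite values in `x`.")
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) abort("`x` has zero variance; kurtosis is undefined.")
  mean((x / sqrt(v))^4) - 3
}

#' Davies-Bouldin cluster validity index
#'
#' For component scores with known sample classes, measures how compact and
#' well separated the classes are: for each class the worst ratio of summed
#' within-class scatters to between-centroid distance is averaged over
#' classes. Lower is better. Scatter \eqn{\sigma_i} is the mean Euclidean
#' distance of class members to their centroid, and centroid distances are
#' Euclidean in the component space, so the index is invariant to rotation
#' and translation of the scores.
#'
#' @param scores an n x m numeric matrix or data frame of component
#'   coordinates.
#' @param labels a length-n vector of class labels with at least two
#'   distinct classes.
#' @return the index (non-negative scalar).
#' @examples
#' s <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' davies_bouldin(s, c("a", "a", "b", "b"))  # (1 + 1) / 10 = 0.2
#' @export
davies_bouldin <- function(scores, labels) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (any(!is.finite(scores))) abort("non-finite values in `scores`.")
  labels <- as.factor(labels)
  if (length(labels) != nrow(scores)) {
    abort("`labels` must have one entry per row of `scores`.")
  }
  k <- nlevels(droplevels(labels))
  if (k < 2L) abort("need at least two classes.")
  labels <- droplevels(labels)
  cent <- t(vapply(levels(labels), function(l) {
    colMeans(scores[labels == l, , drop = FALSE])
  }, numeric(ncol(scores))))
  sig <- vapply(seq_len(k), function(i) {
    d <- sweep(scores[labels == levels(labels)[i], , drop = FALSE], 2,
               cent[i, ], `-`)
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  dd <- as.matrix(stats::dist(cent))
  if (any(dd[upper.tri(dd)] == 0)) {
    abort("coincident class centroids; the index is undefined.")
  }
  ratio <- outer(sig, sig, `+`) / dd
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

#' Angle between a true and an estimated loading vector
#'
#' Sign-invariant principal angle in degrees,
#' \eqn{\arccos(|\langle v, \hat v\rangle| / (\|v\| \|\hat v\|))},
#' in \[0, 90\]. Sign invariance matters because SVD and ICA loading signs
#' are arbitrary.
#'
#' @param true_v,estimated_v non-zero numeric vectors of equal length.
#' @return the angle in degrees.
#' @examples
#' loading_angle(c(1, 0), c(0, 1))  # 90
#' loading_angle(c(1, 1), c(-1, -1))  # 0
#' @export
loading_angle <- function(true_v, estimated_v) {
  if (length(true_v) != length(estimated_v)) {
    abort("vectors must have equal length.")
  }
  na <- sqrt(sum(true_v^2)); nb <- sqrt(sum(estimated_v^2))
  if (na == 0 || nb == 0) abort("zero vector has no direction.")
  acos(min(1, abs(sum(true_v * estimated_v)) / (na * nb))) * 180 / pi
}

#' Correct-identification rate of a variable selection
#'
#' Percentage of a true support (the indices of genuinely non-zero loading
#' entries) recovered by a sparse method's selected variable set.
#'
#' @param true_support integer indices (or names) of the true non-zero
#'   variables.
#' @param selected integer indices (or names) selected by the method; must
#'   be non-empty.
#' @return a percentage in \[0, 100\].
#' @examples
#' identification_rate(1:50, c(1:25, 101:125))  # 50
#' @export
identification_rate <- function(true_support, selected) {
  if (length(selected) == 0L) abort("`selected` is empty.")
  if (length(true_support) == 0L) abort("`true_support` is empty.")
  100 * length(intersect(true_support, selected)) / length(true_support)
}
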