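fit_fixture <- function(seed = 5, ncomp = 3, ...) {
  d <- sim_fixture(seed = 31)
  list(d = d, fit = ipca_fit(d$data, ncomp = ncomp, seed = seed,
                             tol = 1e-4, max_iter = 200, ...))
}

test_that("independent loadings are standardized, ordered and self-consistent", {
  fx <- fit_fixture()
  fit <- fx$fit
  p <- ncol(fx$d$data)
  ## zero mean, unit population variance per loading column
  expect_equal(unname(colMeans(fit$loadings)), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(apply(fit$loadings, 2, function(x) mean((x - mean(x))^2))),
               rep(1, 3), tolerance = 1e-6)
  ## kurtosis non-increasing and recomputable from the stored loadings
  expect_true(all(diff(fit$kurtosis) <= 0))
  expect_equal(fit$kurtosis, unname(apply(fit$loadings, 2, kurtosis_excess)))
  ## projection consistency: recomputed scores match bit for bit
  xc <- center_columns(fx$d$data)
  expect_identical(unname(fit$scores), unname(xc %*% fit$loadings))
})

test_that("ipca is deterministic given a seed", {
  d <- sim_fixture(seed = 31)
  f1 <- ipca_fit(d$data, ncomp = 2, seed = 8, tol = 1e-4, max_iter = 200)
  f2 <- ipca_fit(d$data, ncomp = 2, seed = 8, tol = 1e-4, max_iter = 200)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$scores, f2$scores)
})

test_that("ipca recovers planted super-Gaussian eigenvectors better than chance", {
  d <- sim_fixture(seed = 57)
  fit <- ipca_fit(d$data, ncomp = 2, seed = 1, tol = 1e-4, max_iter = 200)
  a1 <- loading_angle(d$true_v1, fit$loadings[, 1])
  a2 <- loading_angle(d$true_v2, fit$loadings[, 2])
  expect_lt(a1, 25)
  expect_lt(a2, 25)
  ## the planted loadings are spiky: large leading kurtosis
  expect_gt(fit$kurtosis[1], 10)
})

test_that("when loadings are already independent Laplace signals, ipca spans the pca subspace", {
  ## build X = U D V' with two sparse-Laplace orthonormal loading columns
  set.seed(12)
  p <- 300; n <- 40
  v1 <- numeric(p); v1[1:30] <- laplace_sample(30, 1)
  v2 <- numeric(p); v2[151:180] <- laplace_sample(30, 2)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  u <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  x <- u %*% (t(cbind(v1, v2)) * c(30, 20)) + matrix(rnorm(n * p, sd = 0.05), n, p)
  fit <- ipca_fit(x, ncomp = 2, seed = 3)
  pfit <- pca_fit(x, ncomp = 2)
  ## principal angles between the two 2-dim loading subspaces
  qa <- qr.Q(qr(fit$loadings)); qb <- qr.Q(qr(pfit$loadings))
  angles <- acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
  expect_true(all(angles < 5))
})

test_that("sipca applies the exact sparsity plan after kurtosis ordering", {
  d <- sim_fixture("sparse_super_gaussian", seed = 41)
  keepX <- c(40, 25)
  fit <- sipca_fit(d$data, ncomp = 2, keepX = keepX, seed = 2,
                   tol = 1e-4, max_iter = 200)
  expect_equal(unname(colSums(fit$loadings != 0)), keepX)
  ## gamma is the largest excluded absolute dense loading
  for (j in 1:2) {
    dense <- fit$dense_loadings[, j]
    excluded <- setdiff(seq_along(dense), fit$selected[[j]])
    expect_equal(fit$gamma[j], max(abs(dense[excluded])))
  }
  ## scores are the projection on the sparse loadings
  xc <- center_columns(d$data)
  expect_identical(unname(fit$scores), unname(xc %*% fit$loadings))
  ## kurtosis ordering was not redone after sparsification
  expect_equal(fit$kurtosis,
               unname(apply(fit$dense_loadings, 2, kurtosis_excess)))
  expect_true(all(diff(fit$kurtosis) <= 0))
})

test_that("keepX = p reduces sipca to ipca", {
  d <- sim_fixture(seed = 63, p = 80)
  f_dense <- ipca_fit(d$data, ncomp = 2, seed = 5, tol = 1e-4, max_iter = 200)
  f_sparse <- sipca_fit(d$data, ncomp = 2, keepX = 80, seed = 5,
                        tol = 1e-4, max_iter = 200)
  expect_equal(unname(f_sparse$loadings), unname(f_dense$loadings),
               tolerance = 1e-12)
  expect_equal(unname(f_sparse$scores), unname(f_dense$scores),
               tolerance = 1e-12)
})

test_that("variable selections are nested across decreasing keepX", {
  d <- sim_fixture("sparse_gaussian", seed = 19)
  keeps <- c(100, 50, 20)
  fits <- lapply(keeps, function(k) {
    sipca_fit(d$data, ncomp = 2, keepX = k, seed = 7, tol = 1e-4,
              max_iter = 200)
  })
  for (j in 1:2) {
    for (i in 2:length(keeps)) {
      expect_true(all(fits[[i]]$selected[[j]] %in% fits[[i - 1]]$selected[[j]]))
    }
  }
})

test_that("kurtosis_drop reports values and successive differences", {
  fx <- fit_fixture(ncomp = 5)
  rep1 <- kurtosis_drop(fx$fit)
  expect_equal(rep1$kurtosis, fx$fit$kurtosis)
  expect_equal(rep1$drop, c(0, -diff(fx$fit$kurtosis)))
  ## a sudden drop after the two planted components
  expect_gt(rep1$drop[3], 10)
  expect_lt(rep1$kurtosis[3], 1)
  ## deterministic across runs
  rep2 <- kurtosis_drop(ipca_fit(fx$d$data, ncomp = 5, seed = 5,
                                 tol = 1e-4, max_iter = 200))
  expect_identical(rep1, rep2)
})

test_that("parameter validation matches the fastica preconditions", {
  d <- sim_fixture(seed = 31, p = 40)
  expect_error(ipca_fit(d$data, ncomp = 1), "ncomp")
  expect_error(ipca_fit(d$data, ncomp = 60), "ncomp")
  expect_error(sipca_fit(d$data, ncomp = 2, keepX = c(10, 10, 10)), "keepX")
  expect_error(sipca_fit(d$data, ncomp = 2, keepX = 99), "keepX")
})

test_that("ipca agrees with the reference implementation on a strong-signal fixture", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  d <- sim_fixture(seed = 87)
  mine <- ipca_fit(d$data, ncomp = 2, seed = 2, tol = 1e-4, max_iter = 200)
  ref <- mixOmics::ipca(d$data, ncomp = 2, mode = "deflation")
  cc <- abs(cor(mine$loadings, ref$loadings$X))
  ## each of my independent loadings matches one reference loading
  expect_true(all(apply(cc, 1, max) > 0.99))
})
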