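test_that("classical ica recovers mixed super-Gaussian score signals", {
  ## two Laplace sample-space signals mixed into six variables
  set.seed(2)
  n <- 400
  s1 <- laplace_sample(n, 1); s2 <- laplace_sample(n, 2)
  a1 <- rnorm(6); a2 <- rnorm(6)
  x <- cbind(s1) %*% rbind(a1) + cbind(s2) %*% rbind(a2) +
    matrix(rnorm(n * 6, sd = 0.01), n, 6)
  fit <- ica_fit(x, ncomp = 2, seed = 4)
  cc <- abs(cor(fit$scores, cbind(s1, s2)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  ## ICs are zero mean, unit variance, ordered by kurtosis
  expect_equal(unname(colMeans(fit$scores)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(fit$scores, 2, function(s) mean(s^2))), c(1, 1),
               tolerance = 1e-6)
  expect_true(all(diff(fit$kurtosis) <= 0))
})

test_that("a full-rank ica rotation preserves the whitened geometry", {
  set.seed(6)
  x <- matrix(rnorm(60 * 8), 60, 8)
  fit <- suppressWarnings(ica_fit(x, ncomp = 8, seed = 1, max_iter = 300))
  s <- fit$scores
  ## rotation of whitened components: still uncorrelated with unit variance
  expect_equal(crossprod(s) / nrow(s), diag(8), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## loadings are unit-norm directions
  expect_equal(unname(colSums(fit$loadings^2)), rep(1, 8), tolerance = 1e-8)
})

test_that("ica loading directions regenerate the ICs by projection", {
  d <- sim_fixture(seed = 23)
  fit <- suppressWarnings(ica_fit(d$data, ncomp = 2, n_whiten = 5, seed = 9,
                                  tol = 1e-4, max_iter = 200))
  xc <- center_columns(d$data)
  proj <- xc %*% fit$loadings
  for (j in 1:2) {
    expect_gt(abs(cor(proj[, j], fit$scores[, j])), 1 - 1e-8)
  }
})

test_that("spca with keepX = p reproduces the pca loadings", {
  set.seed(8)
  x <- matrix(rnorm(40 * 15), 40, 15)
  sp <- spca_fit(x, ncomp = 3, keepX = 15, scale = FALSE)
  pc <- pca_fit(x, ncomp = 3)
  for (j in 1:3) {
    dotp <- abs(sum(sp$loadings[, j] * pc$loadings[, j]))
    expect_equal(dotp, 1, tolerance = 1e-6)
  }
})

test_that("spca recovers a planted sparse rank-1 support exactly", {
  set.seed(10)
  n <- 60; p <- 120
  v <- numeric(p); v[sample(p, 10)] <- rnorm(10, sd = 2) + sign(rnorm(10)) * 2
  u <- rnorm(n)
  x <- u %*% t(v) + matrix(rnorm(n * p, sd = 0.05), n, p)
  fit <- spca_fit(x, ncomp = 1, keepX = 10, scale = FALSE)
  expect_setequal(fit$selected[[1]], which(v != 0))
  expect_equal(unname(colSums(fit$loadings != 0)), 10)
  ## unit norm on the support
  expect_equal(sum(fit$loadings[, 1]^2), 1, tolerance = 1e-10)
})

test_that("spca separates the planted sparse eigenvector pair", {
  d <- sim_fixture("sparse_gaussian", seed = 4)
  fit <- spca_fit(d$data, ncomp = 2, keepX = 50)
  expect_equal(unname(colSums(fit$loadings != 0)), c(50, 50))
  ## each planted support is mostly recovered by one of the two components
  r1 <- max(identification_rate(d$support1, fit$selected[[1]]),
            identification_rate(d$support1, fit$selected[[2]]))
  r2 <- max(identification_rate(d$support2, fit$selected[[1]]),
            identification_rate(d$support2, fit$selected[[2]]))
  expect_gt(r1, 60)
  expect_gt(r2, 60)
})

test_that("baselines are deterministic under a fixed seed", {
  d <- sim_fixture(seed = 77, p = 100)
  i1 <- ica_fit(d$data, ncomp = 2, seed = 3, tol = 1e-4, max_iter = 200)
  i2 <- ica_fit(d$data, ncomp = 2, seed = 3, tol = 1e-4, max_iter = 200)
  expect_identical(i1$loadings, i2$loadings)
  s1 <- spca_fit(d$data, ncomp = 2, keepX = 20)
  s2 <- spca_fit(d$data, ncomp = 2, keepX = 20)
  expect_identical(s1$loadings, s2$loadings)
})
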