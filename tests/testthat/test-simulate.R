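test_that("designs validate their parameters", {
  d <- sim_design("gaussian")
  expect_equal(c(d$n, d$p, d$c1, d$c2, d$c_rest), c(50, 500, 400, 300, 1))
  expect_equal(d$support1, 1:50)
  expect_equal(d$support2, 301:350)
  d2 <- sim_design("super_gaussian", p = 100)
  expect_equal(d2$p, 100)
  expect_equal(length(d2$support1), 10)
  expect_error(sim_design("gaussian", c1 = 300, c2 = 400), "c1 >= c2")
  expect_error(sim_design("banana"), "arg")
  expect_error(sim_design("gaussian", p = 2), "p")
})

test_that("the planted covariance has the prescribed spectrum", {
  design <- sim_design("super_gaussian", p = 120)
  cv <- build_covariance(design, seed = 3)
  expect_equal(crossprod(cv$V), diag(120), tolerance = 1e-10,
               ignore_attr = TRUE)
  ev <- eigen(cv$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1:2], c(400, 300), tolerance = 1e-6)
  expect_equal(ev[3:120], rep(1, 118), tolerance = 1e-6)
  ## sigma = V C V' reconstruction
  rec <- cv$V %*% (t(cv$V) * cv$eigenvalues)
  expect_lt(norm(cv$sigma - rec, "F") / norm(cv$sigma, "F"), 1e-10)
  ## equal trailing eigenvalues collapse sigma to the rank-2 form
  rank2 <- diag(120) + 399 * tcrossprod(cv$true_v1) +
    299 * tcrossprod(cv$true_v2)
  expect_lt(norm(cv$sigma - rank2, "F") / norm(cv$sigma, "F"), 1e-10)
})

test_that("sparse cases plant disjoint, already-orthogonal supports", {
  design <- sim_design("sparse_super_gaussian")
  d <- sim_dataset(design, seed = 5)
  expect_true(all(d$true_v1[-design$support1] == 0))
  expect_true(all(d$true_v2[-design$support2] == 0))
  expect_equal(sum(d$true_v1 * d$true_v2), 0)
  expect_equal(sum(d$true_v1^2), 1, tolerance = 1e-12)
  expect_equal(sum(d$true_v2^2), 1, tolerance = 1e-12)
})

test_that("datasets are deterministic given the seed", {
  design <- sim_design("gaussian", p = 60)
  d1 <- sim_dataset(design, seed = 9)
  d2 <- sim_dataset(design, seed = 9)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$true_v1, d2$true_v1)
  d3 <- sim_dataset(design, seed = 10)
  expect_false(identical(d1$data, d3$data))
})

test_that("the sample covariance reflects the planted eigenvalues", {
  design <- sim_design("gaussian")
  evs <- vapply(1:5, function(s) {
    d <- sim_dataset(design, seed = s)
    xc <- scale(d$data, center = TRUE, scale = FALSE)
    svd(xc, nu = 0, nv = 0)$d[1]^2 / (design$n - 1)
  }, numeric(1))
  ## leading sample eigenvalue is of order 400 (Monte-Carlo range over seeds)
  expect_true(all(evs > 250 & evs < 650))
})

test_that("replicate reports are deterministic, tidy and recomputable", {
  design <- sim_design("super_gaussian", p = 100)
  r1 <- run_replicates(design, methods = c("pca", "ipca"), n_reps = 4,
                       seed = 2)
  r2 <- run_replicates(design, methods = c("pca", "ipca"), n_reps = 4,
                       seed = 2)
  expect_identical(r1$replicates, r2$replicates)
  expect_named(r1$replicates,
               c("replicate", "method", "metric", "component", "value"))
  expect_equal(r1$n_failed, 0)
  ## aggregates recomputable from the stored per-replicate values
  for (k in seq_len(nrow(r1$summary))) {
    s <- r1$summary[k, ]
    v <- r1$replicates$value[r1$replicates$method == s$method &
                             r1$replicates$metric == s$metric &
                             r1$replicates$component == s$component]
    expect_equal(s$mean, mean(v))
    expect_equal(s$median, median(v))
    expect_equal(s$sd, sd(v))
    expect_equal(s$n, length(v))
  }
})

test_that("sparse-method replicates score identification against the planted supports", {
  design <- sim_design("sparse_gaussian", p = 200)
  r <- run_replicates(design, methods = c("spca", "sipca"), n_reps = 3,
                      keepX = 20, ncomp_kurtosis = NULL, seed = 5)
  expect_setequal(unique(r$replicates$method), c("spca", "sipca"))
  expect_true(all(r$replicates$metric == "id_rate"))
  expect_true(all(r$replicates$value >= 0 & r$replicates$value <= 100))
})
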