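## fixtures shared across test files; everything built in code, seeded

## unit-variance Laplace sample
laplace_sample <- function(q, seed) {
  set.seed(seed)
  u <- runif(q, -0.5, 0.5)
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

## two Laplace sources mixed by a rotation; the standard ICA recovery fixture
mixed_laplace_pair <- function(q = 2000, theta = pi / 6, seed = 42) {
  s <- rbind(laplace_sample(q, seed), laplace_sample(q, seed + 1))
  list(sources = s, mixed = rotation2(theta) %*% s)
}

## maximum absolute correlation matching of recovered to true sources
recovery_cor <- function(recovered, truth) {
  cc <- abs(cor(t(recovered), t(truth)))
  apply(cc, 2, max)
}

## small super-Gaussian benchmark dataset
sim_fixture <- function(case = "super_gaussian", seed = 11, ...) {
  sim_dataset(sim_design(case, ...), seed = seed)
}
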