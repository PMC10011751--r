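test_that("loading and latent effect follow the target-correlation algebra", {
  expect_equal(round_half_up(loading_from_target(0.4), 3), 0.632)
  expect_equal(loading_from_target(1), 1)
  expect_equal(loading_from_target(0.25), 0.5)
  expect_equal(round_half_up(latent_effect(0.5, 0.4), 3), 0.791)
  expect_equal(latent_effect(0, 0.7), 0)
  expect_equal(latent_effect(0.3, 1), 0.3)
  # loading times latent shift recovers the outcome effect identically
  for (r in c(0.2, 0.5, 0.9)) {
    expect_equal(loading_from_target(r) * latent_effect(0.5, r), 0.5)
  }
  expect_error(loading_from_target(0), "latent factor")
  expect_error(latent_effect(0.5, 0), "latent factor")
})

test_that("config validation enforces the generative constraints", {
  expect_error(sim_config("L1", 6, 50, target_mean_r = 0), "latent factor")
  expect_error(sim_config("L9", 6, 50, target_mean_r = 0.4))
  expect_error(sim_config("L1", 1, 50, target_mean_r = 0.4))
  expect_error(sim_config("L1", 6, 1, target_mean_r = 0.4))
  expect_error(sim_config("L1", 6, 50, effect_size = -1,
                          target_mean_r = 0.4))
  cfg <- sim_config("L2x", 5, 20, 0.3, 0.5, n_sims = 100, seed = 7)
  expect_s3_class(cfg, "sim_config")
  expect_output(print(cfg), "L2x")
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- sim_config("L2", 6, 30, 0.5, 0.4, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$outcomes, d2$outcomes)
  d3 <- simulate_dataset(cfg, seed = 12)
  expect_false(identical(d1$outcomes, d3$outcomes))
})

test_that("L1 datasets hit the target correlation, unit variance and effect", {
  d <- simulate_dataset(sim_config("L1", 6, 10000, 0, 0.4, seed = 21))
  R <- cor(d$outcomes)
  expect_equal(mean(R[upper.tri(R)]), 0.4, tolerance = 0.02)
  n <- length(d$group)
  # sampling SE of a unit variance is sqrt(2/n); allow ~3.5 SEs per outcome
  expect_true(all(abs(apply(d$outcomes, 2, var) - 1) < 5 / sqrt(n)))

  d <- simulate_dataset(sim_config("L1", 4, 100000, 0.5, 0.4, seed = 22))
  ci <- d$group == "I"
  delta <- colMeans(d$outcomes[ci, ]) - colMeans(d$outcomes[!ci, ])
  expect_true(all(abs(delta - 0.5) < 0.02))
})

test_that("two-factor models are independent across blocks", {
  d <- simulate_dataset(sim_config("L2", 8, 10000, 0, 0.8, seed = 23))
  R <- cor(d$outcomes)
  n <- length(d$group)
  cross <- R[1:4, 5:8]
  expect_true(all(abs(cross) < 3 / sqrt(n)))
  within <- c(R[1:4, 1:4][upper.tri(diag(4))], R[5:8, 5:8][upper.tri(diag(4))])
  expect_equal(mean(within), 0.8, tolerance = 0.02)
  # overall mean off-diagonal matches the block-counting prediction
  expect_equal(mean(R[upper.tri(R)]), block_mean_offdiag(8, 0.8),
               tolerance = 0.02)
})

test_that("L2x confines the effect to the first block; odd k splits ceil/floor", {
  d <- simulate_dataset(sim_config("L2x", 5, 20000, 0.5, 0.4, seed = 24))
  ci <- d$group == "I"
  delta <- colMeans(d$outcomes[ci, ]) - colMeans(d$outcomes[!ci, ])
  # first block = V1..V3 (ceil(5/2)), second = V4..V5
  expect_true(all(delta[1:3] > 0.4))
  expect_true(all(abs(delta[4:5]) < 3 / sqrt(10000)))
  # under L2 both blocks carry the effect
  d2 <- simulate_dataset(sim_config("L2", 5, 20000, 0.5, 0.4, seed = 25))
  ci <- d2$group == "I"
  delta2 <- colMeans(d2$outcomes[ci, ]) - colMeans(d2$outcomes[!ci, ])
  expect_true(all(abs(delta2 - 0.5) < 0.05))
})

test_that("population_corr reflects the generative structure", {
  expect_equal(population_corr(sim_config("L1", 6, 10, target_mean_r = 0.4)),
               equicorrelated_matrix(6, 0.4))
  expect_equal(population_corr(sim_config("L2x", 5, 10, target_mean_r = 0.3)),
               block_matrix(c(3, 2), 0.3))
})

test_that("first principal component behaves as a composite score", {
  # perfectly correlated pair: PC1 proportional to either outcome
  d <- simulate_dataset(sim_config("L1", 2, 500, 0, 1, seed = 31))
  s <- pca_first_component(d)
  expect_equal(abs(cor(s, d$outcomes[, 1])), 1, tolerance = 1e-8)

  # near-independent outcomes: PC1 explains about 1/m of the variance
  # (slightly above at finite n: the leading sample eigenvalue of an
  # identity population is biased upward by ~2 sqrt(m/n))
  set.seed(32)
  x <- matrix(rnorm(50000 * 5), ncol = 5)
  s <- pca_first_component(x)
  expect_equal(var(s) / sum(apply(x, 2, var)), 1 / 5, tolerance = 0.05)

  # strong common factor: leading sample eigenvalue near 1 + (k-1) r
  d <- simulate_dataset(sim_config("L1", 6, 10000, 0, 0.8, seed = 33))
  ev1 <- max(eigen(cor(d$outcomes), symmetric = TRUE)$values)
  expect_equal(ev1, 5.0, tolerance = 0.1)

  # sign convention: positive group effect gives higher mean PC1 score in I
  d <- simulate_dataset(sim_config("L1", 4, 2000, 0.8, 0.4, seed = 34))
  s <- pca_first_component(d)
  expect_gt(mean(s[d$group == "I"]), mean(s[d$group == "C"]))

  expect_error(pca_first_component(d, m = 1))
  expect_error(pca_first_component(d, m = 9))
})

test_that("dataset CSV export writes subjects, groups and a config sidecar", {
  cfg <- sim_config("L2", 4, 10, 0.5, 0.4, seed = 41)
  d <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcome_dataset(d, path)
  back <- read.csv(path)
  expect_equal(names(back), c("subject_id", "group", paste0("V", 1:4)))
  expect_equal(nrow(back), 20)
  expect_equal(back$group, rep(c("C", "I"), each = 10))
  expect_equal(unname(as.matrix(back[paste0("V", 1:4)])),
               unname(d$outcomes), tolerance = 1e-6)
  meta <- readLines(paste0(path, ".meta.txt"))
  expect_true(any(grepl("model = L2", meta)))
  expect_true(any(grepl("seed = 41", meta)))
  expect_true(any(grepl("loading = 0.632", meta)))
})
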