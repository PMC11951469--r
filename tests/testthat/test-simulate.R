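test_that("simulation is deterministic given a seed and honors its invariants", {
  cfg <- sim_config(n_control = 80, n_treated = 60, seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  expect_equal(s1$observed$times, pmin(s1$latent_T, s1$latent_C))
  expect_equal(s1$observed$events, as.numeric(s1$latent_T <= s1$latent_C))
  expect_equal(sum(s1$observed$treatment == 0), 80)
  expect_true(all(s1$r_values > 0 & s1$r_values <= 1))
})

test_that("mean control latent time matches the exponential-mean oracle", {
  # E[T | X] = r(X) + 1, so E[T] = E[r] + 1 with E[r] from an independent draw
  set.seed(6)
  Xo <- matrix(rnorm(3e5, mean = 1), 1e5, 3)
  r_oracle <- exp(-(-0.2 * (pi * Xo[, 1] * Xo[, 2]) + 0.3 * Xo[, 3]^3)^2)
  target <- mean(r_oracle) + 1
  cfg <- sim_config(n_control = 20000, n_treated = 2, seed = 7)
  sim <- simulate_dataset(cfg)
  t_ctl <- sim$latent_T[sim$observed$treatment == 0]
  expect_lt(abs(mean(t_ctl) - target), 3 * sd(t_ctl) / sqrt(length(t_ctl)))
})

test_that("event fractions agree with the competing-exponential-rates oracle", {
  # P(event | X) = lambda_T / (lambda_T + lambda_C) averaged over X
  set.seed(8)
  Xo <- matrix(rnorm(3e5, mean = 1), 1e5, 3)
  lamT <- 1 / (exp(-(-0.2 * pi * Xo[, 1] * Xo[, 2] + 0.3 * Xo[, 3]^3)^2) + 1)
  p_ctl <- mean(lamT / (lamT + 1.75))
  X1 <- sweep(Xo, 2, c(1, -0.5, 0.1), "+")
  lamT1 <- 1 / (2 * (exp(-(-0.3 * cos(pi * X1[, 2] * X1[, 3]) + 0.1 * X1[, 1]^2)^2) + 1))
  p_trt <- mean(lamT1 / (lamT1 + 1.5))
  fr <- event_rates(sim_config(seed = 9), n_reps = 10) / 100
  mc_se <- sqrt(p_ctl * (1 - p_ctl) / (10 * 1000))
  expect_lt(abs(fr[["control"]] - p_ctl), 3 * mc_se + 0.005)
  mc_se_t <- sqrt(p_trt * (1 - p_trt) / (10 * 800))
  expect_lt(abs(fr[["treated"]] - p_trt), 3 * mc_se_t + 0.005)
})

test_that("true gain is zero at the origin and under a null configuration", {
  cfg <- sim_config(seed = 10)
  d <- true_gain(cfg, c(0, 0.5, 1), seed = 10)
  expect_identical(d[1], 0)
  expect_error(true_gain(cfg, 0:1, n_mc = 100), "10000")
})

test_that("true gain matches direct high-resolution integration at a grid point", {
  cfg <- sim_config(seed = 11)
  t0 <- 1.2
  d_mc <- true_gain(cfg, t0, n_mc = 4e5, seed = 11)
  # independent oracle: quasi-exhaustive Monte Carlo with antithetic normals
  set.seed(99)
  Z <- matrix(rnorm(3 * 3e5), 3e5, 3)
  Z <- rbind(Z, -Z)
  p0 <- 1000 / 1800
  X0 <- Z + 1
  X1 <- sweep(Z, 2, 1 + cfg$shifts, "+")
  s_t <- function(X, arm) {
    if (arm == 0) mean(exp(-t0 * (1 / (r_ctl_oracle(X) + 1))))
    else mean(exp(-t0 / (2 * (r_trt_oracle(X) + 1))))
  }
  r_ctl_oracle <- function(X) exp(-(-0.2 * pi * X[, 1] * X[, 2] + 0.3 * X[, 3]^3)^2)
  r_trt_oracle <- function(X) exp(-(-0.3 * cos(pi * X[, 2] * X[, 3]) + 0.1 * X[, 1]^2)^2)
  d_oracle <- p0 * (s_t(X0, 1) - s_t(X0, 0)) + (1 - p0) * (s_t(X1, 1) - s_t(X1, 0))
  expect_lt(abs(d_mc - d_oracle), 0.005)
})

test_that("randomized scenario removes covariate shift and censoring when asked", {
  sim <- simulate_randomized(400, cens_rate = 1e-9, seed = 12)
  expect_true(all(sim$observed$events == 1))
  m0 <- colMeans(sim$observed$covariates[sim$observed$treatment == 0, ])
  m1 <- colMeans(sim$observed$covariates[sim$observed$treatment == 1, ])
  expect_lt(max(abs(m0 - m1)), 4 / sqrt(400))
})

test_that("benchmark runner reports a perfect oracle method as near zero", {
  # metric sanity: feeding the true gain back in yields ~0 integrated error
  cfg <- sim_config(n_control = 200, n_treated = 160, seed = 13)
  set.seed(13)
  sim <- simulate_dataset(cfg)
  tau <- quantile(sim$observed$times, 0.95, names = FALSE)
  grid <- seq(0, tau, length.out = 50)
  d1 <- true_gain(cfg, grid, n_mc = 5e4, seed = 1)
  d2 <- true_gain(cfg, grid, n_mc = 5e4, seed = 2)
  expect_lt(mse_metric(grid, d1, d2), 1e-3)
})

test_that("benchmark table is reproducible and bookkeeps failures", {
  cfg <- sim_config(n_control = 120, n_treated = 100, seed = 14)
  b1 <- run_benchmark(cfg, methods = "cse", n_reps = 3)
  b2 <- run_benchmark(cfg, methods = "cse", n_reps = 3)
  expect_equal(b1, b2)
  expect_equal(b1$failures, 0)
  expect_equal(b1$n_reps, 3)
  expect_true(is.finite(b1$mean_x100) && b1$mean_x100 >= 0)
})
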