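test_that("survival_dataset validates schema", {
  expect_error(survival_dataset(c(1, -1), c(1, 1), c(0, 1), matrix(0, 2, 1)),
               "positive")
  expect_error(survival_dataset(c(1, 2), c(1, 2), c(0, 1), matrix(0, 2, 1)),
               "0/1")
  expect_error(survival_dataset(c(1, 2), c(1, 1), c(0, 2), matrix(0, 2, 1)),
               "0/1")
  expect_error(survival_dataset(c(1, 2), c(1, 1), c(0, 1), matrix(NA_real_, 2, 1)),
               "finite")
  d <- survival_dataset(c(1, 2), c(1, 1), c(0, 1), cbind(c(0.5, 1)))
  expect_s3_class(d, "survival_dataset")
})

test_that("scalar ridge systems reduce to their closed forms", {
  ks <- kernel_spec(bandwidth = 1)
  ls <- kernel_spec(bandwidth = 1)
  eps <- 0.3
  # n = 1, uncensored, target covariate equal to source: a = 1 / (1 + eps)
  emb <- counterfactual_embedding(2, 1, 0.4, 0.4, ks, ls, epsilon = eps)
  expect_equal(emb$coefficients, 1 / (1 + eps))
  expect_equal(evaluate_embedding(emb, 2), 1 / (1 + eps))

  # solver interface: (1 + eps) c = h for a single unit-weight observation
  solver <- fit_cme_coefficients(matrix(1), 1, eps)
  expect_equal(solver(1), 1 / (1 + eps))
  expect_error(fit_cme_coefficients(matrix(1), 1, -1), "positive")
  expect_error(fit_cme_coefficients(matrix(1), 0, 0.1), "zero")
})

test_that("no censoring reduces to the uncensored CME ridge solution", {
  set.seed(8)
  n <- 40; m <- 25
  X <- matrix(rnorm(n * 2), n, 2)
  X1 <- matrix(rnorm(m * 2, 0.3), m, 2)
  tt <- rexp(n) + 0.05
  ks <- kernel_spec(bandwidth = 1.1)
  ls <- kernel_spec(bandwidth = 0.9)
  eps <- 0.05
  emb <- counterfactual_embedding(tt, rep(1, n), X, X1, ks, ls, epsilon = eps)
  K <- gram(X, X, ks)
  Kt <- gram(X, X1, ks)
  a_ref <- solve(K + n * eps * diag(n), rowMeans(Kt))
  expect_lt(max(abs(emb$coefficients - a_ref)), 1e-10)
})

test_that("censored rows get exactly zero coefficients; permutation equivariance", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n), n, 1)
  tt <- rexp(n) + 0.05
  ev <- rbinom(n, 1, 0.6)
  ks <- kernel_spec(bandwidth = 1)
  ls <- kernel_spec(bandwidth = 1)
  emb <- counterfactual_embedding(tt, ev, X, X, ks, ls, epsilon = 0.05)
  expect_identical(emb$coefficients[ev == 0], rep(0, sum(ev == 0)))
  expect_true(all(emb$coefficients[ev == 1] != 0))

  perm <- sample(n)
  emb_p <- counterfactual_embedding(tt[perm], ev[perm], X[perm, , drop = FALSE],
                                    X, ks, ls, epsilon = 0.05)
  grid <- seq(0.1, 3, length.out = 25)
  expect_equal(evaluate_embedding(emb_p, grid), evaluate_embedding(emb, grid),
               tolerance = 1e-10)
})

test_that("evaluate_embedding matches the explicit double loop; ridge limit shrinks to 0", {
  set.seed(10)
  atoms <- rexp(12) + 0.1
  a <- rnorm(12)
  ls <- kernel_spec(bandwidth = 0.7)
  est <- structure(list(atom_times = atoms, coefficients = a, l_spec = ls,
                        epsilon = 0.1, weights = rep(1, 12)),
                   class = "embedding_estimate")
  grid <- runif(8, 0, 3)
  mu <- numeric(8)
  for (j in 1:8) for (i in 1:12) {
    mu[j] <- mu[j] + a[i] * exp(-(atoms[i] - grid[j])^2 / (2 * 0.7^2))
  }
  expect_equal(evaluate_embedding(est, grid), mu, tolerance = 1e-12)

  X <- matrix(rnorm(20), 20, 1)
  tt <- rexp(20) + 0.1
  big <- counterfactual_embedding(tt, rep(1, 20), X, X,
                                  kernel_spec(bandwidth = 1),
                                  kernel_spec(bandwidth = 1), epsilon = 1e6)
  expect_lt(sqrt(sum(big$coefficients^2)), 1e-4)
  expect_lt(max(abs(evaluate_embedding(big, seq(0, 3, length.out = 11)))), 1e-3)
})

test_that("covariance-operator route (Woodbury inversion) agrees with the closed form", {
  set.seed(12)
  n <- 10; m <- 6
  X <- matrix(rnorm(n), n, 1)
  X1 <- matrix(rnorm(m, 0.4), m, 1)
  tt <- rexp(n) + 0.1
  ev <- rbinom(n, 1, 0.7); ev[1] <- 1
  ks <- kernel_spec(bandwidth = 0.8)
  ls <- kernel_spec(bandwidth = 0.6)
  eps <- 0.07
  emb <- counterfactual_embedding(tt, ev, X, X1, ks, ls, epsilon = eps)
  w <- emb$weights

  # mu = Ctx (Cxx + eps I)^{-1} mu_X1 with the finite-rank empirical operators,
  # inverting through the Woodbury identity on the n-dimensional section
  K <- gram(X, X, ks)
  u <- rowMeans(gram(X, X1, ks))              # mu_X1 evaluated at the X_i
  alpha <- solve(eps * diag(n) + K %*% diag(w) / n, u)
  g_at_X <- (u - drop(K %*% (w * alpha)) / n) / eps
  b <- (w / n) * g_at_X                        # atom coefficients of Ctx g
  grid <- seq(0.05, 4, length.out = 30)
  mu_op <- drop(gram(grid, tt, ls) %*% b)
  expect_lt(max(abs(mu_op - evaluate_embedding(emb, grid))), 1e-10)
})

test_that("closed form minimizes the weighted empirical risk (generic minimizer oracle)", {
  set.seed(13)
  for (trial in 1:3) {
    n <- sample(2:5, 1)
    # separated points keep the Gram matrices well conditioned so the
    # generic minimizer can be pushed to convergence
    X <- matrix(sort(runif(n, 0, 4)) + 0.6 * seq_len(n), n, 1)
    tt <- sort(runif(n, 0.2, 4)) + 0.6 * seq_len(n)
    w <- runif(n, 0.5, 2) * rbinom(n, 1, 0.8)
    if (all(w == 0)) w[1] <- 1
    eps <- 0.15
    ks <- kernel_spec(bandwidth = 1)
    ls <- kernel_spec(bandwidth = 1)
    K <- gram(X, X, ks)
    L <- gram(tt, tt, ls)
    gamma_closed <- solve(diag(w) %*% K + n * eps * diag(n)) %*% diag(w)
    gamma_num <- risk_minimizer_cg(K, L, w, eps)
    expect_lt(fspace_norm(gamma_num - gamma_closed, K, L), 1e-8)
    # perturbations in random directions do not decrease the risk
    for (r in 1:3) {
      D <- matrix(rnorm(n * n), n, n) * 1e-3
      expect_gte(risk_value(K, L, w, eps, gamma_closed + D),
                 risk_value(K, L, w, eps, gamma_closed) - 1e-12)
    }
  }
})

test_that("degenerate inputs are rejected", {
  ks <- kernel_spec(bandwidth = 1); ls <- kernel_spec(bandwidth = 1)
  expect_error(counterfactual_embedding(c(1, 2), c(0, 0), matrix(0:1), matrix(1),
                                        ks, ls, epsilon = 0.1),
               "fully censored")
  expect_error(counterfactual_embedding(c(1, 2), c(1, 1), matrix(0:1),
                                        matrix(1, 1, 2), ks, ls, epsilon = 0.1),
               "dimensions differ")
})
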