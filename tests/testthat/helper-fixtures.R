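# Shared fixtures, built in code.

# the 5-observation worked example: events at 1, 2, 4, 5; censored at 3
fixture_five <- function() {
  list(times = c(1, 2, 3, 4, 5), events = c(1, 1, 0, 1, 1))
}

# small censored two-arm dataset with 1-d covariates
toy_dataset <- function(n = 40, seed = 1, p = 1, cens_rate = 0.5) {
  set.seed(seed)
  z <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * p, mean = 1 + 0.5 * z), n, p)
  tt <- rexp(n, rate = 1 / (1 + 0.5 * z))
  cc <- rexp(n, rate = cens_rate)
  survival_dataset(pmin(tt, cc), as.numeric(tt <= cc), z, x)
}

# RKHS norm of the difference of two finite expansions, by Gram matrices
expansion_distance <- function(t1, a1, t2, a2, l_spec) {
  sq <- drop(crossprod(a1, gram(t1, t1, l_spec) %*% a1)) +
    drop(crossprod(a2, gram(t2, t2, l_spec) %*% a2)) -
    2 * drop(crossprod(a1, gram(t1, t2, l_spec) %*% a2))
  sqrt(max(sq, 0))
}

# Generic first-order minimizer of the weighted regularized empirical risk
# over coefficient matrices gamma (F(x) = sum_j k(x, X_j) sum_k gamma_jk
# l(T_k, .)). Independent of the closed-form linear-system solution: uses
# only gradient evaluations of the risk functional (expressed through Gram
# matrices) inside a conjugate-gradient descent with exact line search,
# which is exact for this quadratic risk.
risk_gradient <- function(K, L, w, epsilon) {
  n <- nrow(K)
  dw <- w / n
  function(g) {
    G <- matrix(g, n, n)
    as.vector(2 * K %*% ((dw * (K %*% G - diag(n))) + epsilon * G) %*% L)
  }
}

risk_value <- function(K, L, w, epsilon, g) {
  n <- nrow(K)
  G <- matrix(g, n, n)
  M <- K %*% G
  ML <- M %*% L
  sum((w / n) * (diag(L) - 2 * diag(ML) + diag(ML %*% t(M)))) +
    epsilon * sum(K * (G %*% L %*% t(G)))
}

risk_minimizer_cg <- function(K, L, w, epsilon) {
  n <- nrow(K)
  grad <- risk_gradient(K, L, w, epsilon)
  b <- grad(rep(0, n * n))          # gradient is affine: grad(x) = H x + b
  matvec <- function(v) grad(v) - b
  x <- rep(0, n * n)
  r <- -b
  p <- r
  rs <- sum(r * r)
  rs0 <- rs
  for (iter in seq_len(200L * n * n)) {
    if (rs < 1e-26 * max(rs0, 1)) break
    Ap <- matvec(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  matrix(x, n, n)
}

# F-space norm of a coefficient-matrix difference:
# ||dF||^2 = sum_{ij} K_ij <row_i L ., row_j>
fspace_norm <- function(D, K, L) {
  sqrt(max(sum(K * (D %*% L %*% t(D))), 0))
}
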