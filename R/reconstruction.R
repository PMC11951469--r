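# Recovering a survival curve from a kernel mean embedding estimate.
#
# plugin: transfer the ridge coefficients from kernel features to survival
#   indicator features, S(t) = 1 - sum_{atom <= t} a_i, then clip to [0, 1]
#   and project onto the non-increasing cone (pool-adjacent-violators).
# simplex: find the probability vector p on the uncensored atoms whose
#   embedding is RKHS-closest to the estimate, min_p p'Lp - 2 p'La over the
#   probability simplex; the implied survival curve is monotone by
#   construction.

#' Reconstruct a survival function from an embedding estimate
#'
#' @param est An `embedding_estimate` with at least one nonzero coefficient.
#' @param method `"plugin"` (default) or `"simplex"`; see Details.
#' @param tail Tail convention for the plugin method. `"deficit"` (default)
#'   anchors the curve at 1 and subtracts the coefficient mass as atoms are
#'   passed, so any missing mass `1 - sum(a)` persists as a tail plateau —
#'   the same convention by which the product-limit estimator carries its
#'   plateau past the last event under censoring. `"zero"` evaluates
#'   `S(t) = sum_{atom > t} a_i`, which starts at `sum(a)` and vanishes
#'   beyond the last atom (the complete-data empirical-survival behavior).
#' @param max_iter,tol Iteration controls for the simplex quadratic program
#'   (accelerated projected gradient).
#' @details The plugin method reads the ridge coefficients as Riesz weights
#'   of the embedded distribution and evaluates them against indicator
#'   features, the same transfer that turns inverse-censoring weights into
#'   product-limit survival estimates; antitonic projection repairs any
#'   local non-monotonicity without renormalizing. The simplex method
#'   instead projects the embedding onto the set of embeddings of
#'   probability measures supported on the uncensored atoms, a small convex
#'   QP solved by accelerated projected gradient.
#' @return A [step_survival()].
#' @export
reconstruct_survival <- function(est, method = c("plugin", "simplex"),
                                 tail = c("deficit", "zero"),
                                 max_iter = 2000L, tol = 1e-12) {
  stopifnot(inherits(est, "embedding_estimate"))
  method <- match.arg(method)
  tail <- match.arg(tail)
  active <- which(est$coefficients != 0)
  if (!length(active)) stop("embedding estimate has no active atoms", call. = FALSE)
  at <- est$atom_times[active]
  a <- est$coefficients[active]
  switch(method,
         plugin = reconstruct_plugin(at, a, tail),
         simplex = reconstruct_simplex(at, a, est$l_spec, max_iter, tol))
}

reconstruct_plugin <- function(atom_times, coefs, tail = "deficit") {
  ord <- order(atom_times)
  t_s <- atom_times[ord]
  c_s <- coefs[ord]
  # aggregate tied atoms
  s <- unique(t_s)
  mass <- vapply(split(c_s, match(t_s, s)), sum, numeric(1))
  init <- if (tail == "deficit") 1 else sum(mass)
  lev <- c(init, init - cumsum(mass))  # value before 1st jump, then after each
  lev <- pmin(pmax(lev, 0), 1)
  # antitonic projection: PAVA for a non-increasing fit
  lev <- -stats::isoreg(seq_along(lev), -lev)$yf
  lev <- pmin(pmax(lev, 0), 1)
  step_survival(s, lev[-1L], init = lev[1L])
}

# Euclidean projection onto the probability simplex (sort-based).
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

reconstruct_simplex <- function(atom_times, coefs, l_spec, max_iter, tol) {
  L <- gram(atom_times, atom_times, l_spec)
  q <- drop(L %*% coefs)
  m <- length(coefs)
  # Lipschitz constant of the gradient via power iteration on L
  v <- rep(1 / sqrt(m), m)
  for (i in 1:60) {
    v <- drop(L %*% v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  lip <- 2 * max(nv, 1e-12) * 1.01
  # FISTA on f(p) = p'Lp - 2 p'q over the simplex
  p <- proj_simplex(coefs)
  y <- p
  tt <- 1
  for (iter in seq_len(max_iter)) {
    g <- 2 * (drop(L %*% y) - q)
    p_new <- proj_simplex(y - g / lip)
    t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    y <- p_new + ((tt - 1) / t_new) * (p_new - p)
    delta <- max(abs(p_new - p))
    p <- p_new
    tt <- t_new
    if (delta < tol) break
  }
  ord <- order(atom_times)
  t_s <- atom_times[ord]
  p_s <- p[ord]
  s <- unique(t_s)
  mass <- vapply(split(p_s, match(t_s, s)), sum, numeric(1))
  vals <- sum(mass) - cumsum(mass)
  vals <- pmin(pmax(vals, 0), 1)
  vals <- rev(cummax(rev(vals)))  # guard round-off monotonicity
  step_survival(s, vals, init = 1)
}
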