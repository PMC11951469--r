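#' Right-censored observational survival dataset
#'
#' One row per subject: observed time `T* = min(T, C)`, event indicator
#' `Delta`, treatment arm `Z` and numeric covariates `X`.
#'
#' @param times Positive observed times.
#' @param events 0/1 event indicators.
#' @param treatment 0/1 treatment indicators (0 = control).
#' @param covariates Numeric matrix or data frame, one row per subject.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(times, events, treatment, covariates) {
  check_rc_sample(times, events)
  covariates <- as_point_matrix(covariates)
  n <- length(times)
  if (length(treatment) != n || nrow(covariates) != n) {
    stop("times, events, treatment and covariates must have matching rows",
         call. = FALSE)
  }
  if (!all(treatment %in% c(0, 1))) {
    stop("treatment indicators must be 0/1", call. = FALSE)
  }
  if (anyNA(covariates) || any(!is.finite(covariates))) {
    stop("covariates must be finite and complete", call. = FALSE)
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("X", seq_len(ncol(covariates)))
  }
  structure(list(times = as.numeric(times), events = as.numeric(events),
                 treatment = as.numeric(treatment), covariates = covariates),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d subjects (%d control / %d treated), %d covariate(s), %.1f%% events\n",
              length(x$times), sum(x$treatment == 0), sum(x$treatment == 1),
              ncol(x$covariates), 100 * mean(x$events)))
  invisible(x)
}

arm_rows <- function(data, arm) which(data$treatment == arm)

# Solve (W_U K_UU + n*eps*I) x_U = W_U rhs_U on the positive-weight rows U and
# embed back with exact zeros elsewhere. Rows with W_i = 0 decouple (their
# equation reads n*eps*c_i = 0), which both guarantees zero coefficients on
# censored atoms and shrinks the dense solve to the uncensored subsample.
cme_solve <- function(K_uu, w_u, n, epsilon, rhs_u) {
  A <- w_u * K_uu
  diag(A) <- diag(A) + n * epsilon
  solve(A, w_u * rhs_u)
}

#' Censored conditional mean embedding ridge solve
#'
#' Returns the linear-solve operator at the heart of the embedding estimator:
#' the map `rhs -> (W K + n eps I)^{-1} W rhs`, where `K` is the covariate
#' Gram matrix of the source sample and `W = diag(weights)` holds the IPCW
#' weights. Applying it to the column means of the cross Gram matrix against
#' the target covariates yields the counterfactual embedding coefficients.
#'
#' @param K Source covariate Gram matrix (n x n).
#' @param weights Non-negative weights, at least one positive.
#' @param epsilon Positive ridge regularization; the matrix carries `n*epsilon`
#'   on the diagonal.
#' @return A function taking a length-n vector (or n-row matrix) and returning
#'   the solved coefficients, exactly zero on zero-weight rows.
#' @export
fit_cme_coefficients <- function(K, weights, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a positive scalar", call. = FALSE)
  }
  n <- nrow(K)
  if (n != ncol(K) || n != length(weights)) {
    stop("`K` must be square with one row per weight", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  u <- which(weights > 0)
  if (!length(u)) stop("all weights are zero: no usable observations", call. = FALSE)
  K_uu <- K[u, u, drop = FALSE]
  w_u <- weights[u]
  function(rhs) {
    rhs <- as.matrix(rhs)
    if (nrow(rhs) != n) stop("right-hand side has wrong length", call. = FALSE)
    out <- matrix(0, n, ncol(rhs))
    out[u, ] <- cme_solve(K_uu, w_u, n, epsilon, rhs[u, , drop = FALSE])
    drop(out)
  }
}

default_epsilon <- function(n) 0.1 * n^(-1 / 3)

#' Counterfactual mean embedding estimator
#'
#' Estimates the kernel mean embedding of the counterfactual distribution
#' obtained by carrying the source arm's conditional survival law over to the
#' target arm's covariate distribution. The conditional embedding is fit by
#' IPCW-weighted vector-valued kernel ridge regression on the source arm
#' (weights `W_i = Delta_i / G_hat(T*_i-)` from the reverse Kaplan-Meier
#' estimator), then averaged over the target covariates:
#' coefficients `a = W (K W + n eps I)^{-1} Ktilde 1_m`, so the embedding is
#' `mu_hat(t) = sum_i a_i l(T*_i, t)`. Censored source rows receive
#' coefficient exactly 0.
#'
#' @param times,events Source-arm observed times and event indicators.
#' @param covariates Source-arm covariate matrix.
#' @param target_covariates Covariate matrix of the opposite arm.
#' @param k_spec,l_spec [kernel_spec()] for the covariate kernel k and time
#'   kernel l; default is the median heuristic on the pooled covariates and
#'   the source times respectively.
#' @param epsilon Ridge regularization; default `0.1 * n^(-1/3)`, inside the
#'   admissible window of the consistency theory.
#' @param censoring_floor Floor for the censoring survival, see
#'   [ipcw_weights()].
#' @param weight_scheme `"ipcw"` for the censoring-corrected estimator or
#'   `"event"` for the naive variant that keeps raw event indicators as
#'   weights (no censoring correction).
#' @return An object of class `embedding_estimate` with fields `atom_times`,
#'   `coefficients`, `l_spec`, `k_spec`, `epsilon`, `weights`.
#' @export
counterfactual_embedding <- function(times, events, covariates, target_covariates,
                                     k_spec = NULL, l_spec = NULL, epsilon = NULL,
                                     censoring_floor = 1e-10,
                                     weight_scheme = c("ipcw", "event")) {
  check_rc_sample(times, events)
  weight_scheme <- match.arg(weight_scheme)
  covariates <- as_point_matrix(covariates)
  target_covariates <- as_point_matrix(target_covariates)
  n <- length(times)
  if (nrow(covariates) != n) stop("covariate rows must match times", call. = FALSE)
  if (!nrow(target_covariates)) stop("target covariates are empty", call. = FALSE)
  if (ncol(covariates) != ncol(target_covariates)) {
    stop("source and target covariate dimensions differ", call. = FALSE)
  }
  if (all(events == 0)) {
    stop("source arm is fully censored: no usable atoms", call. = FALSE)
  }
  if (is.null(k_spec)) {
    k_spec <- kernel_spec(bandwidth = median_heuristic(rbind(covariates,
                                                             target_covariates)))
  }
  if (is.null(l_spec)) {
    l_spec <- kernel_spec(bandwidth = median_heuristic(times))
  }
  if (is.null(epsilon)) epsilon <- default_epsilon(n)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)

  w <- switch(weight_scheme,
              ipcw = ipcw_weights(times, events,
                                  reverse_kaplan_meier(times, events),
                                  floor = censoring_floor),
              event = as.numeric(events))
  u <- which(w > 0)
  K_uu <- gram(covariates[u, , drop = FALSE], covariates[u, , drop = FALSE], k_spec)
  r_u <- rowMeans(gram(covariates[u, , drop = FALSE], target_covariates, k_spec))
  a <- numeric(n)
  a[u] <- cme_solve(K_uu, w[u], n, epsilon, r_u)
  structure(list(atom_times = as.numeric(times), coefficients = a,
                 l_spec = l_spec, k_spec = k_spec, epsilon = epsilon,
                 weights = w, weight_scheme = weight_scheme),
            class = "embedding_estimate")
}

#' Evaluate an embedding estimate on a time grid
#'
#' `mu_hat(t_j) = sum_i a_i l(atom_i, t_j)`.
#'
#' @param est An `embedding_estimate`.
#' @param grid Numeric vector of times.
#' @return Numeric vector of embedding values.
#' @export
evaluate_embedding <- function(est, grid) {
  stopifnot(inherits(est, "embedding_estimate"))
  if (!length(grid)) stop("grid must be nonempty", call. = FALSE)
  drop(gram(grid, est$atom_times, est$l_spec) %*% est$coefficients)
}

#' RKHS distance between two embedding estimates
#'
#' Exact RKHS norm of the difference of two weighted-atom expansions,
#' computed through Gram matrices of the shared time kernel.
#'
#' @param est_a,est_b `embedding_estimate` objects with identical time kernels.
#' @return Non-negative scalar distance.
#' @export
embedding_distance <- function(est_a, est_b) {
  stopifnot(inherits(est_a, "embedding_estimate"),
            inherits(est_b, "embedding_estimate"))
  if (abs(est_a$l_spec$bandwidth - est_b$l_spec$bandwidth) > 1e-12) {
    stop("embeddings live in different RKHSs (time bandwidths differ)",
         call. = FALSE)
  }
  ia <- which(est_a$coefficients != 0)
  ib <- which(est_b$coefficients != 0)
  a <- est_a$coefficients[ia]; ta <- est_a$atom_times[ia]
  b <- est_b$coefficients[ib]; tb <- est_b$atom_times[ib]
  sq <- 0
  if (length(a)) sq <- sq + drop(crossprod(a, gram(ta, ta, est_a$l_spec) %*% a))
  if (length(b)) sq <- sq + drop(crossprod(b, gram(tb, tb, est_a$l_spec) %*% b))
  if (length(a) && length(b)) {
    sq <- sq - 2 * drop(crossprod(a, gram(ta, tb, est_a$l_spec) %*% b))
  }
  sqrt(max(sq, 0))
}

#' @export
print.embedding_estimate <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("embedding estimate: %d atoms (%d active), epsilon = %.4g, time bandwidth = %.4g\n",
              length(x$atom_times), nz, x$epsilon, x$l_spec$bandwidth))
  invisible(x)
}
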