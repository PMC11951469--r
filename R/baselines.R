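#' Naive (uncensored-only) counterfactual curves
#'
#' Same pipeline as [estimate_effect_curves()] but with embedding weights set
#' to the raw event indicators `W_i = Delta_i`: censored observations are
#' discarded without inverse-censoring correction. With no censoring it
#' coincides with the corrected estimator; under censoring it is biased and
#' less stable because it ignores the selection induced by censoring.
#'
#' @inheritParams estimate_effect_curves
#' @return An `effect_curves` object.
#' @export
naive_effect_curves <- function(data, grid = NULL, epsilon = NULL,
                                bandwidth_k = NULL, bandwidth_l = NULL,
                                method = c("plugin", "simplex"),
                                grid_size = 50L) {
  estimate_effect_curves(data, grid = grid, epsilon = epsilon,
                         bandwidth_k = bandwidth_k, bandwidth_l = bandwidth_l,
                         method = match.arg(method),
                         weight_scheme = "event", grid_size = grid_size)
}

akme_propensity <- function(data, truncation = c(0.01, 0.99)) {
  df <- as.data.frame(data$covariates)
  df$.z <- data$treatment
  fit <- stats::glm(.z ~ ., data = df, family = stats::binomial())
  e <- stats::fitted(fit)
  if (any(e > 1 - 1e-8) || any(e < 1e-8)) {
    stop("propensity model separation: fitted probabilities reach 0/1",
         call. = FALSE)
  }
  pmin(pmax(e, truncation[1]), truncation[2])
}

#' Adjusted (IPTW) Kaplan-Meier survival curve
#'
#' The AKME baseline: a linear logistic regression of treatment on the
#' covariates provides propensity scores `e(x)`; subjects are weighted by
#' `1/e(x)` in the treated arm and `1/(1 - e(x))` in the control arm, and a
#' weighted product-limit estimator is computed within the requested arm.
#' Propensities are truncated to `[0.01, 0.99]` to guard against the extra
#' variance that extreme inverse weights introduce.
#'
#' @param data A [survival_dataset()] containing both arms.
#' @param arm Which arm's adjusted curve to return (0 or 1).
#' @param weights Optional per-subject weights for the rows of `arm`,
#'   bypassing the logistic fit (useful for fixed-weight analyses).
#' @param truncation Propensity truncation bounds.
#' @return A [step_survival()].
#' @export
akme_survival <- function(data, arm, weights = NULL,
                          truncation = c(0.01, 0.99)) {
  stopifnot(inherits(data, "survival_dataset"), arm %in% c(0, 1))
  rows <- arm_rows(data, arm)
  if (!length(rows)) stop("requested arm is empty", call. = FALSE)
  if (is.null(weights)) {
    if (!length(arm_rows(data, 1 - arm))) {
      stop("both arms are required to estimate the propensity score", call. = FALSE)
    }
    e <- akme_propensity(data, truncation)
    weights <- if (arm == 1) 1 / e[rows] else 1 / (1 - e[rows])
  } else if (length(weights) != length(rows)) {
    stop("`weights` must have one entry per subject in the arm", call. = FALSE)
  }
  kaplan_meier(data$times[rows], data$events[rows], weights = weights)
}

#' AKME counterfactual gain curve
#'
#' Difference of the two IPTW-adjusted Kaplan-Meier curves on a grid,
#' `d_hat(t) = S_akme_1(t) - S_akme_0(t)`.
#'
#' @inheritParams akme_survival
#' @param grid Time grid.
#' @return Numeric vector of gain values on `grid`.
#' @export
akme_gain <- function(data, grid, truncation = c(0.01, 0.99)) {
  s1 <- akme_survival(data, 1, truncation = truncation)
  s0 <- akme_survival(data, 0, truncation = truncation)
  eval_step(s1, grid) - eval_step(s0, grid)
}
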