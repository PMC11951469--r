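#' Right-continuous step survival function
#'
#' A piecewise-constant survival curve: value `init` (1 for product-limit
#' estimators) before the first jump, `values[j]` on
#' `[jump_times[j], jump_times[j+1])`. Reconstruction from a kernel mean
#' embedding may start below 1, hence the explicit `init`.
#'
#' @param jump_times Strictly increasing positive jump locations (may be empty).
#' @param values Curve value attained at (and right of) each jump; must be
#'   non-increasing and lie in `[0, 1]`.
#' @param init Value on `[0, jump_times[1])`; defaults to 1.
#' @return An object of class `step_survival`.
#' @export
step_survival <- function(jump_times, values, init = 1) {
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values)) {
    stop("`jump_times` and `values` must have equal length", call. = FALSE)
  }
  if (length(jump_times)) {
    if (any(jump_times <= 0)) stop("jump times must be positive", call. = FALSE)
    if (is.unsorted(jump_times, strictly = TRUE)) {
      stop("jump times must be strictly increasing", call. = FALSE)
    }
  }
  v <- c(init, values)
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(v) > 1e-12)) stop("survival values must be non-increasing", call. = FALSE)
  structure(list(jump_times = jump_times,
                 values = pmin(pmax(values, 0), 1),
                 init = min(max(init, 0), 1)),
            class = "step_survival")
}

#' Evaluate a step survival function
#'
#' @param s A [step_survival()].
#' @param t Numeric vector of evaluation times.
#' @param side `"right"` for the right-continuous value S(t) (default),
#'   `"left"` for the left limit S(t-) used by IPCW weighting.
#' @return Numeric vector of survival values.
#' @export
eval_step <- function(s, t, side = c("right", "left")) {
  stopifnot(inherits(s, "step_survival"))
  side <- match.arg(side)
  v <- c(s$init, s$values)
  idx <- findInterval(t, s$jump_times, left.open = (side == "left"))
  v[idx + 1L]
}

#' @export
print.step_survival <- function(x, ...) {
  cat(sprintf("step survival function with %d jumps", length(x$jump_times)))
  if (length(x$jump_times)) {
    cat(sprintf(" on [%.4g, %.4g], final value %.4g",
                min(x$jump_times), max(x$jump_times),
                x$values[length(x$values)]))
  }
  cat("\n")
  invisible(x)
}

check_rc_sample <- function(times, events) {
  if (length(times) == 0L) stop("empty sample", call. = FALSE)
  if (length(times) != length(events)) {
    stop("`times` and `events` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all observed times must be positive and finite", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("event indicators must be 0/1", call. = FALSE)
  invisible(NULL)
}

survfit_to_step <- function(fit) {
  keep <- fit$n.event > 0
  step_survival(fit$time[keep], fit$surv[keep])
}

#' Kaplan-Meier estimator
#'
#' Standard product-limit estimator of the survival function of the event
#' time; ties between events and censorings at the same time are resolved
#' with events first (the `survival` package convention). Censored-only
#' times induce no jump.
#'
#' @param times Positive observed times `T* = min(T, C)`.
#' @param events 0/1 event indicators (1 = event observed).
#' @param weights Optional positive case weights (weighted product-limit).
#' @return A [step_survival()].
#' @examples
#' km <- kaplan_meier(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 1))
#' eval_step(km, c(2, 4))  # 0.6, 0.3
#' @export
kaplan_meier <- function(times, events, weights = NULL) {
  check_rc_sample(times, events)
  if (is.null(weights)) weights <- rep(1, length(times))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           weights = weights, se.fit = FALSE)
  survfit_to_step(fit)
}

#' Reverse Kaplan-Meier estimator of the censoring distribution
#'
#' Estimates `G(t) = P(C > t)` by flipping the event indicators and applying
#' the product-limit estimator, valid when censoring is independent of the
#' event time within the stratum.
#'
#' @inheritParams kaplan_meier
#' @return A [step_survival()] estimating the censoring survival function.
#' @export
reverse_kaplan_meier <- function(times, events) {
  check_rc_sample(times, events)
  kaplan_meier(times, 1 - events)
}

#' Inverse-probability-of-censoring weights
#'
#' `W_i = Delta_i / G_hat(T*_i -)`, evaluating the censoring survival at the
#' left limit so that an event occurring at the largest observed time keeps a
#' positive weight. Censored observations get weight exactly 0. Weights are
#' floored away from division blow-up: whenever `G_hat(T*_i -) < floor` for
#' an event row the floor is used instead and a warning is emitted, matching
#' the square-integrability condition the estimator needs.
#'
#' @inheritParams kaplan_meier
#' @param g_hat [step_survival()] estimate of the censoring survival,
#'   typically from [reverse_kaplan_meier()] on the same sample.
#' @param floor Lower bound in (0, 1) applied to the censoring survival.
#' @return Numeric vector of non-negative weights.
#' @export
ipcw_weights <- function(times, events, g_hat, floor = 1e-10) {
  check_rc_sample(times, events)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor >= 1) {
    stop("`floor` must lie in (0, 1)", call. = FALSE)
  }
  g_left <- eval_step(g_hat, times, side = "left")
  hit <- events == 1 & g_left < floor
  if (any(hit)) {
    warning(sprintf("censoring survival below floor %g for %d event row(s); floored",
                    floor, sum(hit)))
  }
  ifelse(events == 1, 1 / pmax(g_left, floor), 0)
}
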