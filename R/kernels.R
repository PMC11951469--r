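#' Kernel specification
#'
#' Describes the positive-semidefinite kernel used for the time axis and the
#' covariate space. Only the Gaussian (squared-exponential) family is
#' supported: `exp(-||u - v||^2 / (2 * bandwidth^2))`. Gaussian kernels are
#' bounded, with `k(x, x) = 1`, and their RKHS is dense in the relevant L2
#' space, which is what the consistency theory of the embedding estimator
#' requires.
#'
#' @param family Kernel family; currently only `"gaussian"`.
#' @param bandwidth Positive length-scale sigma.
#' @return An object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec(bandwidth = 1)
#' gram(c(0, 1), c(0, 1), ks)
#' @export
kernel_spec <- function(family = "gaussian", bandwidth) {
  family <- match.arg(family, "gaussian")
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || !is.finite(bandwidth) ||
      bandwidth <= 0) {
    stop("`bandwidth` must be a single positive finite number", call. = FALSE)
  }
  structure(list(family = family, bandwidth = as.numeric(bandwidth)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Gaussian kernel, bandwidth sigma = %g\n", x$bandwidth))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

#' Gram matrix between two point sets
#'
#' Entry (i, j) is `kernel(a_i, b_j)`. Points may be numeric vectors
#' (one-dimensional points) or matrices with one row per point.
#'
#' @param points_a,points_b Numeric vector, matrix or data frame of points
#'   sharing the same dimension.
#' @param spec A [kernel_spec()].
#' @return A `length(a) x length(b)` numeric matrix.
#' @export
gram <- function(points_a, points_b, spec) {
  if (!inherits(spec, "kernel_spec")) stop("`spec` must be a kernel_spec", call. = FALSE)
  a <- as_point_matrix(points_a)
  b <- as_point_matrix(points_b)
  if (ncol(a) != ncol(b)) {
    stop(sprintf("point dimension mismatch: %d vs %d", ncol(a), ncol(b)),
         call. = FALSE)
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  exp(-d2 / (2 * spec$bandwidth^2))
}

#' Median-heuristic bandwidth
#'
#' The median of the Euclidean distances over all distinct pairs of points,
#' the standard default length-scale for kernel mean-embedding methods.
#'
#' @param points Numeric vector or matrix of points (at least two distinct).
#' @return A positive scalar bandwidth.
#' @export
median_heuristic <- function(points) {
  x <- as_point_matrix(points)
  if (nrow(x) < 2L) stop("need at least two points", call. = FALSE)
  med <- stats::median(stats::dist(x))
  if (!is.finite(med) || med <= 0) {
    stop("median pairwise distance is zero: bandwidth undefined (points identical?)",
         call. = FALSE)
  }
  med
}
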