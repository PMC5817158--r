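# Shared ellipse machinery: boundary of {v : (v - m)' Sigma^{-1} (v - m) = r2}
# in 2-D ilr coordinates, mapped back to the simplex. Returns a closed
# polyline (first row repeated last).
.ellipse_boundary <- function(m, Sigma, r2, n_points, basis, parts) {
  ch <- tryCatch(chol(Sigma), error = function(e) {
    abort(paste0(
      "ilr covariance is singular or not positive definite; ",
      "jitter the data or reduce the part set."
    ))
  })
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  pts <- sweep(sqrt(r2) * circ %*% ch, 2, m, "+")
  pts[n_points, ] <- pts[1, ] # exact closure of the polyline
  comp <- .ilr_inv_mat(pts, basis)
  out <- as_tibble(comp)
  names(out) <- parts
  out
}

.ilr_mean_cov <- function(data, parts, basis) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "simplex region")
  v <- .ilr_mat(m, basis)
  list(mean = colMeans(v), cov = stats::cov(v), n = nrow(v))
}

#' Sigma (spread) region on the simplex
#'
#' Ellipse of Mahalanobis radius `k` under the ilr sample covariance of the
#' individual compositions, centred at the ilr mean (the geometric mean
#' composition) and back-transformed to the simplex. It describes the
#' predicted spread of individual compositions: under an ilr-normal
#' (logistic-normal) model a fraction `pchisq(k^2, D - 1)` of points falls
#' inside — about 86.5% at `k = 2` and 98.9% at `k = 3` for three parts.
#'
#' @inheritParams comp_close
#' @param k Sigma multiplier, typically 2 or 3.
#' @param n_points Number of boundary points (closed polyline; the last row
#'   repeats the first). Default 256.
#' @param basis ilr contrast basis; see [ilr_basis()].
#' @return A tibble of boundary compositions (columns `parts`) with
#'   attributes `kind = "sigma"` and `level = k`.
#' @export
sigma_region <- function(data, parts = comp_parts(data), k = 2,
                         n_points = 256, basis = ilr_basis(parts)) {
  if (nrow(data) < 3) abort("sigma_region() needs at least 3 compositions.")
  if (!is.numeric(k) || k <= 0) abort("`k` must be a positive number.")
  mc <- .ilr_mean_cov(data, parts, basis)
  out <- .ellipse_boundary(mc$mean, mc$cov, k^2, n_points, basis, parts)
  attr(out, "kind") <- "sigma"
  attr(out, "level") <- k
  out
}

#' Confidence region for the mean composition
#'
#' Hotelling-T2 confidence ellipse for the geometric mean: centred at the
#' ilr mean with shape `cov / N`, and squared Mahalanobis radius
#' `(D-1)(N-1) / (N-(D-1)) * qf(coverage, D-1, N-(D-1))`, back-transformed
#' to the simplex. Unlike [sigma_region()] this describes uncertainty in
#' the mean and shrinks as `1/sqrt(N)`.
#'
#' @inheritParams sigma_region
#' @param coverage Confidence level, e.g. 0.90 or 0.99.
#' @return A tibble of boundary compositions with attributes
#'   `kind = "confidence"` and `level = coverage`.
#' @export
confidence_region <- function(data, parts = comp_parts(data), coverage = 0.90,
                              n_points = 256, basis = ilr_basis(parts)) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    abort("`coverage` must lie strictly between 0 and 1.")
  }
  q <- length(parts) - 1
  n <- nrow(data)
  if (n <= q + 1) {
    abort(sprintf(
      "confidence_region() needs N > D (here N = %d, D = %d) for the F construction.",
      n, length(parts)
    ))
  }
  mc <- .ilr_mean_cov(data, parts, basis)
  r2 <- q * (n - 1) / (n - q) * stats::qf(coverage, q, n - q)
  out <- .ellipse_boundary(mc$mean, mc$cov / n, r2, n_points, basis, parts)
  attr(out, "kind") <- "confidence"
  attr(out, "level") <- coverage
  out
}

#' Test whether a mean lies inside the Hotelling confidence region
#'
#' Convenience predicate used for coverage checks: `TRUE` when the
#' hypothesised mean composition falls inside the `coverage` confidence
#' region of the sample mean.
#'
#' @inheritParams confidence_region
#' @param mean One-row data frame: the hypothesised mean composition.
#' @return Logical scalar.
#' @export
mean_in_confidence_region <- function(data, mean, parts = comp_parts(data),
                                      coverage = 0.90, basis = ilr_basis(parts)) {
  q <- length(parts) - 1
  n <- nrow(data)
  if (n <= q + 1) abort("Too few rows for the F construction.")
  mc <- .ilr_mean_cov(data, parts, basis)
  mu <- as.numeric(.ilr_mat(.closure_mat(part_matrix(mean, parts)), basis))
  d <- mc$mean - mu
  t2 <- n * sum(d * solve(mc$cov, d))
  t2 <= q * (n - 1) / (n - q) * stats::qf(coverage, q, n - q)
}
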