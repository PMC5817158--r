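#' Closed geometric mean composition
#'
#' The compositional centre of a set of diets: the component-wise geometric
#' mean across rows, re-closed to unit sum. Identical (up to floating point)
#' to back-transforming the arithmetic mean of the clr coordinates; both
#' routes are computed and checked against each other internally.
#'
#' @inheritParams comp_close
#' @return A one-row tibble of part columns summing to 1.
#' @examples
#' comp_mean(data.frame(P = c(0.5, 0.2), C = c(0.3, 0.3), L = c(0.2, 0.5)))
#' @export
comp_mean <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "geometric mean")
  g <- exp(colMeans(log(m)))
  g <- g / sum(g)
  # second route: clr average back-transformed
  g2 <- .clr_inv_mat(matrix(colMeans(.clr_mat(m)), 1))
  stopifnot(max(abs(g - g2)) < 1e-9)
  out <- as_tibble(as.list(g))
  names(out) <- parts
  out
}

#' Geometric mean pairwise ratio matrix
#'
#' Entry (i, j) is the exponential of the mean log-ratio
#' `mean(log(x_i / x_j))` across rows — equivalently the ratio `g_i / g_j`
#' of the closed geometric mean's parts (both routes computed and checked).
#' The matrix has unit diagonal and reciprocal symmetry:
#' `m[i, j] * m[j, i] = 1`.
#'
#' @inheritParams comp_close
#' @return A `D x D` numeric matrix with `parts` as dimnames.
#' @export
mean_ratio_matrix <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "mean ratio matrix")
  lg <- colMeans(log(m))
  out <- exp(outer(lg, lg, "-"))
  g <- as.numeric(comp_mean(data, parts)[1, ])
  stopifnot(max(abs(out - outer(g, g, "/"))) < 1e-9)
  dimnames(out) <- list(parts, parts)
  out
}

#' Variation matrix of pairwise log-ratios
#'
#' Entry (i, j) is the sample variance (denominator `N - 1`) of
#' `log(x_i / x_j)` across rows: the standard dispersion summary for
#' compositional data. Entries near zero mean the two parts move
#' proportionally (are codependent); large entries mean their ratio varies
#' widely across rows. Symmetric with zero diagonal, and invariant to
#' row-wise rescaling before closure.
#'
#' @inheritParams comp_close
#' @return A `D x D` numeric matrix with `parts` as dimnames. With a single
#'   row the matrix is all zeros and a warning is issued.
#' @export
variation_matrix <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "variation matrix")
  D <- ncol(m)
  out <- matrix(0, D, D, dimnames = list(parts, parts))
  if (nrow(m) < 2) {
    warn("variation_matrix() needs at least 2 rows; returning a zero matrix.")
    return(out)
  }
  lm_ <- log(m)
  for (i in seq_len(D - 1)) {
    for (j in seq(i + 1, D)) {
      v <- stats::var(lm_[, i] - lm_[, j])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Total metric (Aitchison) variance
#'
#' One-number dispersion summary: `sum(variation_matrix) / (2 * D)`, equal
#' to the trace of the clr covariance matrix and to the sum of the
#' compositional PCA eigenvalues.
#'
#' @inheritParams comp_close
#' @return A non-negative number.
#' @export
metric_variance <- function(data, parts = comp_parts(data)) {
  tv <- variation_matrix(data, parts)
  sum(tv) / (2 * length(parts))
}

#' Compositional descriptive summary
#'
#' Bundles the closed geometric mean, the geometric mean pairwise ratio
#' matrix, the variation matrix of pairwise log-ratios and the total metric
#' variance for a set of compositions — the standard descriptive block for
#' a compositional data set.
#'
#' @inheritParams comp_close
#' @return An object of class `comp_summary` with elements `geometric_mean`
#'   (one-row tibble), `mean_ratio_matrix`, `variation_matrix`,
#'   `metric_variance`, `n` and `parts`. Use [generics::tidy()] for a long
#'   tibble of all entries and [generics::glance()] for a one-row overview.
#' @export
comp_summary <- function(data, parts = comp_parts(data)) {
  structure(
    list(
      geometric_mean = comp_mean(data, parts),
      mean_ratio_matrix = mean_ratio_matrix(data, parts),
      variation_matrix = variation_matrix(data, parts),
      metric_variance = metric_variance(data, parts),
      n = nrow(data),
      parts = parts
    ),
    class = "comp_summary"
  )
}

#' @export
print.comp_summary <- function(x, digits = 3, ...) {
  cat("Compositional summary of", x$n, "compositions (",
      paste(x$parts, collapse = ", "), ")\n\n")
  cat("Closed geometric mean:\n")
  print(round(as.numeric(x$geometric_mean[1, ]), digits))
  cat("\nMean ratio matrix (row / column):\n")
  print(round(x$mean_ratio_matrix, digits))
  cat("\nVariation matrix of log-ratios:\n")
  print(round(x$variation_matrix, digits))
  cat("\nTotal metric variance:", round(x$metric_variance, digits), "\n")
  invisible(x)
}

.matrix_to_long <- function(m, value_name) {
  tibble(
    part_1 = rep(rownames(m), times = ncol(m)),
    part_2 = rep(colnames(m), each = nrow(m)),
    "{value_name}" := as.numeric(m)
  )
}

#' @importFrom rlang :=
#' @export
tidy.comp_summary <- function(x, ...) {
  gm <- tibble(
    statistic = "geometric_mean",
    part_1 = x$parts,
    part_2 = NA_character_,
    value = as.numeric(x$geometric_mean[1, ])
  )
  mr <- .matrix_to_long(x$mean_ratio_matrix, "value")
  mr$statistic <- "mean_ratio"
  vm <- .matrix_to_long(x$variation_matrix, "value")
  vm$statistic <- "log_ratio_variance"
  dplyr::bind_rows(gm, mr, vm)[, c("statistic", "part_1", "part_2", "value")]
}

#' @export
glance.comp_summary <- function(x, ...) {
  tibble(
    n = x$n,
    n_parts = length(x$parts),
    metric_variance = x$metric_variance,
    max_log_ratio_variance = max(x$variation_matrix)
  )
}
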