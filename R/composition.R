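#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Default part labels: protein, carbohydrate, lipid energy fractions.
.default_parts <- c("P", "C", "L")

# Extract an N x D numeric matrix of parts from a data frame, preserving
# column order as given in `parts`.
part_matrix <- function(data, parts = comp_parts(data)) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with one column per composition part.")
  }
  missing <- setdiff(parts, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Part column(s) not found in `data`: ",
      paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(data[parts])
  if (nrow(m) == 0) abort("`data` needs at least one row.")
  if (!is.numeric(m)) abort("Part columns must be numeric.")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, parts)
  m
}

# Guess part columns: default labels if present, else all numeric columns.
comp_parts <- function(data) {
  if (all(.default_parts %in% names(data))) {
    return(.default_parts)
  }
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num) < 2) abort("Cannot identify composition part columns.")
  num
}

.check_nonneg <- function(m) {
  if (anyNA(m)) abort("Composition parts must not contain NA.")
  if (any(m < 0)) abort("Composition parts must be non-negative.")
}

.closure_mat <- function(m) {
  .check_nonneg(m)
  s <- rowSums(m)
  if (any(s <= 0)) {
    abort("degenerate composition: at least one row has no positive part")
  }
  m / s
}

#' Close raw part amounts to unit-sum compositions
#'
#' Divides each row of non-negative part amounts by its row total so the
#' parts become fractions summing to one (the closure operation of
#' compositional data analysis). Relative information is preserved: rows
#' that differ only by a positive multiplicative constant close to the same
#' composition.
#'
#' @param data A data frame with one numeric column per part.
#' @param parts Character vector of part column names, in order. Defaults to
#'   `c("P", "C", "L")` (protein, carbohydrate, lipid) when present.
#' @return `data` as a tibble with the part columns replaced by their closed
#'   values; all other columns are kept.
#' @examples
#' comp_close(data.frame(P = 1, C = 1, L = 2))
#' @export
comp_close <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  out <- as_tibble(data)
  out[parts] <- as_tibble(m)
  out
}

#' Multiplicative zero replacement
#'
#' Log-ratio operations require strictly positive parts. Zero parts are
#' replaced by a small fraction `delta` and the non-zero parts of the same
#' row are scaled by `1 - z * delta` (with `z` the number of zeros in the
#' row), then the row is re-closed. Rows without zeros are returned
#' unchanged.
#'
#' @inheritParams comp_close
#' @param delta Replacement fraction for a zero part; must be positive and
#'   small relative to the smallest non-zero part. Default `1e-3`.
#' @return A tibble like `data` with strictly positive, closed part columns.
#'   A warning reports how many zeros were replaced.
#' @export
comp_replace_zeros <- function(data, parts = comp_parts(data), delta = 1e-3) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a single positive number.")
  }
  m <- .closure_mat(part_matrix(data, parts))
  zero <- m == 0
  nzero <- sum(zero)
  if (nzero > 0) {
    z <- rowSums(zero)
    scale <- 1 - z * delta
    if (any(scale <= 0)) abort("`delta` too large for the number of zero parts.")
    m <- m * scale
    m[zero] <- delta
    m <- .closure_mat(m)
    warn(sprintf(
      "Replaced %d zero part(s) with delta = %g (multiplicative replacement).",
      nzero, delta
    ))
  }
  out <- as_tibble(data)
  out[parts] <- as_tibble(m)
  out
}

.check_positive <- function(m, op = "log-ratio transform") {
  if (any(m <= 0)) {
    abort(paste0(
      "Zero or negative parts found; the ", op,
      " requires strictly positive parts. See comp_replace_zeros()."
    ))
  }
}

# clr of a closed positive matrix: log(x) centred within each row.
.clr_mat <- function(m) {
  lm_ <- log(m)
  sweep(lm_, 1, rowMeans(lm_), "-")
}

.clr_inv_mat <- function(v) {
  .closure_mat(exp(v))
}

#' Centred log-ratio (clr) transform and its inverse
#'
#' `comp_clr()` maps each composition to the vector of logs of its parts
#' relative to their geometric mean; the resulting coordinates sum to zero
#' within each row. `comp_clr_inv()` maps any real coordinate vectors back
#' to the simplex via closure of the exponentials, so
#' `comp_clr_inv(comp_clr(x))` recovers `x`.
#'
#' @inheritParams comp_close
#' @return A tibble with the part columns replaced by clr coordinates
#'   (`comp_clr()`) or by closed compositions (`comp_clr_inv()`).
#' @export
comp_clr <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "clr transform")
  out <- as_tibble(data)
  out[parts] <- as_tibble(.clr_mat(m))
  out
}

#' @rdname comp_clr
#' @export
comp_clr_inv <- function(data, parts = comp_parts(data)) {
  m <- part_matrix(data, parts)
  if (anyNA(m)) abort("clr coordinates must not contain NA.")
  out <- as_tibble(data)
  out[parts] <- as_tibble(.clr_inv_mat(m))
  out
}

#' Orthonormal ilr contrast basis
#'
#' Builds the Helmert-type contrast matrix used for the isometric log-ratio
#' transform: `D - 1` rows, each orthonormal and summing to zero, in the
#' given part order. Row `k` contrasts the geometric mean of the first `k`
#' parts against part `k + 1`.
#'
#' @param parts Character vector of part labels (length `D >= 2`).
#' @return A `(D-1) x D` matrix with rownames `ilr1, ilr2, ...` and colnames
#'   `parts`.
#' @export
ilr_basis <- function(parts = .default_parts) {
  D <- length(parts)
  if (D < 2) abort("An ilr basis needs at least two parts.")
  B <- matrix(0, D - 1, D, dimnames = list(paste0("ilr", seq_len(D - 1)), parts))
  for (k in seq_len(D - 1)) {
    B[k, seq_len(k)] <- 1 / sqrt(k * (k + 1))
    B[k, k + 1] <- -k / sqrt(k * (k + 1))
  }
  B
}

.check_basis <- function(basis, D) {
  if (!is.matrix(basis) || nrow(basis) != D - 1 || ncol(basis) != D) {
    abort(sprintf("`basis` must be a %d x %d matrix.", D - 1, D))
  }
  ortho <- basis %*% t(basis)
  if (max(abs(ortho - diag(D - 1))) > 1e-8 || max(abs(rowSums(basis))) > 1e-8) {
    abort("`basis` rows must be orthonormal and sum to zero (clr-space contrasts).")
  }
  invisible(basis)
}

.ilr_mat <- function(m, basis) {
  .clr_mat(m) %*% t(basis)
}

.ilr_inv_mat <- function(v, basis) {
  .clr_inv_mat(v %*% basis)
}

#' Isometric log-ratio (ilr) transform and its inverse
#'
#' Maps compositions to `D - 1` unconstrained real coordinates through an
#' orthonormal contrast basis, so that Euclidean distance between ilr
#' coordinate vectors equals the Aitchison distance between the underlying
#' compositions. `comp_ilr_inv()` undoes the map.
#'
#' @inheritParams comp_close
#' @param basis Orthonormal contrast matrix as produced by [ilr_basis()].
#' @param coords For `comp_ilr_inv()`, the names of the ilr coordinate
#'   columns in `data`.
#' @return `comp_ilr()`: a tibble with the part columns replaced by columns
#'   `ilr1 ... ilr(D-1)`; `comp_ilr_inv()`: a tibble with the coordinate
#'   columns replaced by closed part columns named after the basis parts.
#' @export
comp_ilr <- function(data, parts = comp_parts(data), basis = ilr_basis(parts)) {
  .check_basis(basis, length(parts))
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "ilr transform")
  v <- .ilr_mat(m, basis)
  out <- as_tibble(data)
  out <- out[setdiff(names(out), parts)]
  coord <- as_tibble(v)
  names(coord) <- rownames(basis)
  dplyr::bind_cols(coord, out)
}

#' @rdname comp_ilr
#' @export
comp_ilr_inv <- function(data, coords = paste0("ilr", seq_len(ncol(basis) - 1)),
                         basis = ilr_basis()) {
  .check_basis(basis, ncol(basis))
  missing <- setdiff(coords, names(data))
  if (length(missing) > 0) {
    abort(paste0("ilr coordinate column(s) not found: ", paste(missing, collapse = ", ")))
  }
  v <- as.matrix(data[coords])
  m <- .ilr_inv_mat(v, basis)
  out <- as_tibble(data)
  out <- out[setdiff(names(out), coords)]
  partcols <- as_tibble(m)
  names(partcols) <- colnames(basis)
  dplyr::bind_cols(partcols, out)
}

#' Aitchison distance between compositions
#'
#' The Euclidean distance between clr (equivalently ilr) coordinates: the
#' natural metric of the simplex, invariant to scaling and permutation of
#' parts.
#'
#' @param x,y Data frames of compositions with matching part columns; `y`
#'   may have one row (recycled) or as many rows as `x`.
#' @inheritParams comp_close
#' @return Numeric vector of distances, one per row of `x`.
#' @export
aitchison_dist <- function(x, y, parts = comp_parts(x)) {
  mx <- .closure_mat(part_matrix(x, parts))
  my <- .closure_mat(part_matrix(y, parts))
  .check_positive(mx)
  .check_positive(my)
  cx <- .clr_mat(mx)
  cy <- .clr_mat(my)
  if (nrow(cy) == 1 && nrow(cx) > 1) {
    cy <- cy[rep(1, nrow(cx)), , drop = FALSE]
  }
  if (nrow(cy) != nrow(cx)) abort("`y` must have 1 row or as many rows as `x`.")
  sqrt(rowSums((cx - cy)^2))
}
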