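#' Principal component analysis in Aitchison geometry
#'
#' Eigen-decomposition of the clr covariance matrix (sample covariance,
#' denominator `N - 1`) of a set of compositions, centred at the closed
#' geometric mean. The `D - 1` informative components are directions in clr
#' space (each summing to zero); their eigenvalues sum to the total metric
#' variance of the data. Biplot rays are the loadings scaled by the
#' component standard deviations, so for `D = 3` the Euclidean distance
#' between the arrowheads of two rays equals the standard deviation of the
#' corresponding pairwise log-ratio exactly.
#'
#' @inheritParams comp_close
#' @return An object of class `comp_pca` with elements:
#'   `center` (one-row tibble, the geometric mean), `loadings`
#'   (`D x (D-1)` clr directions, columns `PC1 ...`), `sdev`, `variance`,
#'   `variance_share`, `scores` (`N x (D-1)` tibble), `biplot_rays`
#'   (`D x (D-1)`), `parts`, `n`. Methods: [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()].
#' @export
comp_pca <- function(data, parts = comp_parts(data)) {
  m <- .closure_mat(part_matrix(data, parts))
  .check_positive(m, "compositional PCA")
  n <- nrow(m)
  if (n < 3) abort("comp_pca() needs at least 3 compositions.")
  D <- ncol(m)
  clr <- .clr_mat(m)
  ctr <- colMeans(clr)
  cc <- sweep(clr, 2, ctr, "-")
  S <- crossprod(cc) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  keep <- seq_len(D - 1) # last eigenvalue is the null clr direction (~0)
  vals <- pmax(eig$values[keep], 0)
  vecs <- eig$vectors[, keep, drop = FALSE]
  # fix sign: make the largest-magnitude loading of each component positive
  for (k in seq_along(vals)) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  dimnames(vecs) <- list(parts, paste0("PC", keep))
  scores <- cc %*% vecs
  colnames(scores) <- colnames(vecs)
  rays <- sweep(vecs, 2, sqrt(vals), "*")
  structure(
    list(
      center = comp_mean(data, parts),
      loadings = vecs,
      sdev = sqrt(vals),
      variance = vals,
      variance_share = if (sum(vals) > 0) vals / sum(vals) else vals,
      scores = as_tibble(scores),
      biplot_rays = rays,
      parts = parts,
      n = n
    ),
    class = "comp_pca"
  )
}

#' @export
print.comp_pca <- function(x, digits = 3, ...) {
  cat("Compositional PCA (", x$n, " compositions, parts ",
      paste(x$parts, collapse = ", "), ")\n", sep = "")
  cat("Variance explained:",
      paste0(round(100 * x$variance_share, 1), "%", collapse = ", "), "\n")
  cat("clr loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
tidy.comp_pca <- function(x, matrix = c("eigenvalues", "loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble(
      component = seq_along(x$variance),
      std_dev = x$sdev,
      variance = x$variance,
      percent = 100 * x$variance_share,
      cumulative = 100 * cumsum(x$variance_share)
    ),
    loadings = tibble(
      part = rep(x$parts, times = ncol(x$loadings)),
      component = rep(seq_len(ncol(x$loadings)), each = length(x$parts)),
      loading = as.numeric(x$loadings),
      ray = as.numeric(x$biplot_rays)
    ),
    scores = dplyr::mutate(x$scores, row = dplyr::row_number(), .before = 1)
  )
}

#' @export
glance.comp_pca <- function(x, ...) {
  tibble(
    n = x$n,
    n_components = length(x$variance),
    total_variance = sum(x$variance),
    pc1_percent = 100 * x$variance_share[1]
  )
}

#' Biplot of a compositional PCA
#'
#' Covariance biplot in the plane of the first two components: observation
#' scores as points and clr loading rays as arrows. The distance between
#' two arrowheads ("link") approximates the standard deviation of the
#' log-ratio of the two parts, which is how relative variation between
#' parts is read off the plot.
#'
#' @param object A [comp_pca()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comp_pca <- function(object, ...) {
  if (length(object$variance) < 2) {
    abort("Biplot needs at least two components.")
  }
  sc <- object$scores
  rays <- tibble(
    part = object$parts,
    x = object$biplot_rays[, 1],
    y = object$biplot_rays[, 2]
  )
  pct <- round(100 * object$variance_share[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_segment(
      data = rays,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.02, "npc")),
      colour = "red3"
    ) +
    ggplot2::geom_text(
      data = rays,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12, label = .data$part),
      colour = "red3"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = paste0("PC1 (", pct[1], "%)"),
      y = paste0("PC2 (", pct[2], "%)")
    ) +
    ggplot2::theme_minimal()
}
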