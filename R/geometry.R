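#' Equilateral mixture triangle (EMT) coordinates
#'
#' Maps three-part compositions to the plane of a unit-side equilateral
#' triangle (the conventional ternary diagram): with parts ordered
#' `(p1, p2, p3)`, `x = p2 + p3 / 2` and `y = sqrt(3) / 2 * p3`. The first
#' part's 100% corner sits at the origin, the second at (1, 0) and the
#' third at the apex; the barycentre maps to the centroid. The default
#' part order `(P, C, L)` puts protein bottom-left, carbohydrate
#' bottom-right and lipid on top.
#'
#' @inheritParams comp_close
#' @return `data` as a tibble with added columns `x`, `y`.
#' @export
emt_coords <- function(data, parts = comp_parts(data)) {
  if (length(parts) != 3) abort("Mixture triangles need exactly 3 parts.")
  m <- .closure_mat(part_matrix(data, parts))
  out <- as_tibble(data)
  out$x <- unname(m[, 2] + m[, 3] / 2)
  out$y <- unname(sqrt(3) / 2 * m[, 3])
  out
}

#' Invert EMT coordinates back to compositions
#'
#' @param xy Data frame with columns `x`, `y` inside the unit triangle.
#' @param parts Part labels for the reconstructed composition.
#' @return A tibble of part columns.
#' @export
emt_coords_inv <- function(xy, parts = .default_parts) {
  if (length(parts) != 3) abort("Mixture triangles need exactly 3 parts.")
  p3 <- 2 * xy$y / sqrt(3)
  p2 <- xy$x - xy$y / sqrt(3)
  p1 <- 1 - p2 - p3
  out <- tibble(p1, p2, p3)
  names(out) <- parts
  out
}

#' Right-angled mixture triangle (RMT) coordinates
#'
#' Projects a three-part composition onto two chosen parts; the third is
#' implicit (`1 - x - y`), so the simplex appears as a right triangle.
#'
#' @inheritParams comp_close
#' @param axes Character vector of two distinct part names: the x and y
#'   axes.
#' @return `data` as a tibble with added columns `x`, `y`.
#' @export
rmt_coords <- function(data, parts = comp_parts(data), axes = parts[c(2, 3)]) {
  if (length(parts) != 3) abort("Mixture triangles need exactly 3 parts.")
  if (length(axes) != 2 || axes[1] == axes[2] || !all(axes %in% parts)) {
    abort("`axes` must name two distinct parts.")
  }
  m <- .closure_mat(part_matrix(data, parts))
  out <- as_tibble(data)
  out$x <- unname(m[, axes[1]])
  out$y <- unname(m[, axes[2]])
  out
}

#' Isoportion line (fixed fraction of one part)
#'
#' The locus of compositions whose named part equals `value`: a straight
#' segment across the simplex, used e.g. to draw the 17% protein intake
#' target. With a `band`, the two companion segments at `value +/- band`
#' are returned as well.
#'
#' @param part Part whose fraction is fixed.
#' @param value Fraction in (0, 1).
#' @param parts Full part label vector.
#' @param band Optional half-width of a tolerance band.
#' @return A tibble of segment endpoints (part columns, two rows per
#'   segment) with a `level` column naming each segment's fixed fraction.
#' @export
isoportion_line <- function(part, value, parts = .default_parts, band = NULL) {
  if (!part %in% parts) abort("`part` must be one of `parts`.")
  levels <- value
  if (!is.null(band)) levels <- c(value - band, value, value + band)
  if (any(levels <= 0 | levels >= 1)) {
    abort("Isoportion values (including band edges) must lie strictly in (0, 1).")
  }
  others <- setdiff(parts, part)
  rows <- purrr::map(levels, function(v) {
    seg <- tibble(a = c(v, v), b = c(1 - v, 0), c = c(0, 1 - v))
    names(seg) <- c(part, others)
    seg <- seg[parts]
    seg$level <- v
    seg
  })
  dplyr::bind_rows(rows)
}

#' 1:1 isoproportion line between two parts
#'
#' The locus of compositions with two parts equal: the segment from the
#' third part's 100% corner to the midpoint of the opposite edge. The
#' barycentre lies on every such line.
#'
#' @param pair Character vector of the two (distinct) equal parts.
#' @param parts Full part label vector.
#' @return A tibble of two endpoint compositions.
#' @export
isoproportion_line <- function(pair, parts = .default_parts) {
  if (length(pair) != 2 || pair[1] == pair[2] || !all(pair %in% parts)) {
    abort("`pair` must name two distinct parts.")
  }
  third <- setdiff(parts, pair)
  corner <- tibble(a = 0, b = 0, c = 1)
  names(corner) <- c(pair[1], pair[2], third)
  mid <- tibble(a = 0.5, b = 0.5, c = 0)
  names(mid) <- c(pair[1], pair[2], third)
  dplyr::bind_rows(corner[parts], mid[parts])
}

#' Curvilinear principal-component axis on the simplex
#'
#' The Aitchison geodesic through the PCA centre along one component:
#' straight in ilr coordinates (`centre + t * direction`), back-transformed
#' to the simplex where it appears as a curve in the mixture triangle. `t`
#' is in Aitchison-distance units.
#'
#' @param object A [comp_pca()] fit.
#' @param component Component index (1-based).
#' @param span Numeric range of `t`; defaults to +/- 2.5 standard
#'   deviations of the component.
#' @param n_points Number of polyline points.
#' @param basis ilr basis used for the back-transform.
#' @return A tibble of compositions along the curve with a `t` column.
#' @export
pca_axis_curve <- function(object, component = 1, span = NULL, n_points = 64,
                           basis = ilr_basis(object$parts)) {
  if (!inherits(object, "comp_pca")) abort("`object` must be a comp_pca fit.")
  if (!component %in% seq_along(object$variance)) {
    abort("`component` out of range.")
  }
  span <- span %||% (2.5 * object$sdev[component] * c(-1, 1))
  if (any(!is.finite(span))) abort("`span` must be finite.")
  ctr <- .ilr_mat(part_matrix(object$center, object$parts), basis)
  dir_clr <- object$loadings[, component]
  dir_ilr <- as.numeric(basis %*% dir_clr)
  t <- seq(span[1], span[2], length.out = n_points)
  pts <- sweep(outer(t, dir_ilr), 2, as.numeric(ctr), "+")
  comp <- .ilr_inv_mat(pts, basis)
  out <- as_tibble(comp)
  names(out) <- object$parts
  out$t <- t
  out
}

# Triangle frame for the EMT plot.
.emt_frame <- function(parts) {
  tibble(
    x = c(0, 1, 0.5, 0),
    y = c(0, 0, sqrt(3) / 2, 0),
    corner = c(parts, parts[1])
  )
}

#' Plot diet compositions in an equilateral mixture triangle
#'
#' Renders a ternary (EMT) scene in ggplot2: observation points, optional
#' geometric mean, sigma spread regions, confidence regions for the mean,
#' the protein intake-target band, 1:1 isoproportion lines and curvilinear
#' PCA axes. Corner labels mark 100% of each macronutrient.
#'
#' @inheritParams comp_close
#' @param colour Optional column name used to colour points.
#' @param mean Draw the closed geometric mean (default `TRUE` when `data`
#'   has 2+ rows).
#' @param sigma Numeric vector of sigma multipliers for spread regions
#'   (e.g. `c(2, 3)`), or `NULL`.
#' @param conf Numeric vector of confidence levels for mean regions
#'   (e.g. `c(0.90, 0.99)`), or `NULL`.
#' @param target An [intake_target()] drawn as protein isoportion band, or
#'   `NULL`.
#' @param iso_pairs List of part pairs for 1:1 isoproportion lines, or
#'   `NULL`.
#' @param pca A [comp_pca()] fit whose axis curves are overlaid, or `NULL`.
#' @return A ggplot object.
#' @export
plot_emt <- function(data, parts = comp_parts(data), colour = NULL,
                     mean = nrow(data) >= 2, sigma = NULL, conf = NULL,
                     target = NULL, iso_pairs = NULL, pca = NULL) {
  frame <- .emt_frame(parts)
  pts <- emt_coords(data, parts)
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = frame, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey20") +
    ggplot2::annotate("text",
      x = c(-0.04, 1.04, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
      label = parts, fontface = "bold"
    )
  if (!is.null(sigma)) {
    for (k in sigma) {
      reg <- emt_coords(sigma_region(data, parts, k = k), parts)
      p <- p + ggplot2::geom_path(
        data = reg, ggplot2::aes(x = .data$x, y = .data$y),
        colour = if (k <= 2) "blue3" else "red3", linetype = "dashed"
      )
    }
  }
  if (!is.null(conf)) {
    for (cv in conf) {
      reg <- emt_coords(confidence_region(data, parts, coverage = cv), parts)
      p <- p + ggplot2::geom_path(
        data = reg, ggplot2::aes(x = .data$x, y = .data$y),
        colour = "grey40"
      )
    }
  }
  if (!is.null(target)) {
    band <- emt_coords(
      isoportion_line(parts[1], target$protein_fraction, parts,
                      band = target$band_halfwidth),
      parts
    )
    p <- p + ggplot2::geom_line(
      data = band,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$level,
                   linewidth = .data$level == target$protein_fraction),
      colour = "royalblue"
    ) +
      ggplot2::scale_linewidth_manual(values = c(0.3, 0.8), guide = "none")
  }
  if (!is.null(iso_pairs)) {
    for (pr in iso_pairs) {
      seg <- emt_coords(isoproportion_line(pr, parts), parts)
      p <- p + ggplot2::geom_line(
        data = seg, ggplot2::aes(x = .data$x, y = .data$y),
        colour = "grey50", linetype = "dotted"
      )
    }
  }
  if (!is.null(pca)) {
    for (k in seq_along(pca$variance)) {
      crv <- emt_coords(pca_axis_curve(pca, k), parts)
      p <- p + ggplot2::geom_path(
        data = crv, ggplot2::aes(x = .data$x, y = .data$y),
        colour = "green4"
      )
    }
  }
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data[[colour]]), size = 2
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y), size = 2
    )
  }
  if (isTRUE(mean) && nrow(data) >= 2) {
    gm <- emt_coords(comp_mean(data, parts), parts)
    p <- p + ggplot2::geom_point(
      data = gm, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 17, size = 3, colour = "red3"
    )
  }
  p + ggplot2::coord_fixed() + ggplot2::theme_void()
}

#' Plot diet compositions in a right-angled mixture triangle
#'
#' The RMT companion to [plot_emt()]: two parts on the axes, the third
#' implicit, with the simplex boundary drawn as a right triangle.
#'
#' @inheritParams rmt_coords
#' @param colour Optional column name used to colour points.
#' @return A ggplot object.
#' @export
plot_rmt <- function(data, parts = comp_parts(data), axes = parts[c(2, 3)],
                     colour = NULL) {
  pts <- rmt_coords(data, parts, axes)
  frame <- tibble(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = frame, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey20")
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data[[colour]]), size = 2
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y), size = 2
    )
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0(axes[1], " (fraction)"),
                  y = paste0(axes[2], " (fraction)")) +
    ggplot2::theme_minimal()
}

#' Render a plot to an SVG file
#'
#' Thin wrapper over [grDevices::svg()] for writing mixture-triangle scenes
#' to vector files.
#'
#' @param plot A ggplot object.
#' @param path Output file path (`.svg`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_svg <- function(plot, path, width = 7, height = 6) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}
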