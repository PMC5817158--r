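test_that("EMT coordinates map corners, centroid, and invert exactly", {
  corners <- tibble::tibble(P = c(1, 0, 0), C = c(0, 1, 0), L = c(0, 0, 1))
  xy <- emt_coords(corners)
  expect_equal(xy$x, c(0, 1, 0.5))
  expect_equal(xy$y, c(0, 0, sqrt(3) / 2))
  bary <- emt_coords(tibble::tibble(P = 1/3, C = 1/3, L = 1/3))
  expect_equal(c(bary$x, bary$y), c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  x <- random_comp_set(30, seed = 13)
  back <- emt_coords_inv(emt_coords(x))
  expect_equal(as.matrix(back), as.matrix(x[c("P", "C", "L")]), tolerance = 1e-12)
})

test_that("RMT coordinates project onto the chosen parts", {
  x <- tibble::tibble(P = 0.2, C = 0.3, L = 0.5)
  xy <- rmt_coords(x, axes = c("C", "L"))
  expect_equal(c(xy$x, xy$y), c(0.3, 0.5))
  expect_error(rmt_coords(x, axes = c("C", "C")), "distinct")
})

test_that("isoportion segments intersect the simplex boundary correctly", {
  seg <- isoportion_line("P", 0.17)
  expect_equal(as.matrix(seg[c("P", "C", "L")]),
               matrix(c(0.17, 0.17, 0.83, 0, 0, 0.83), 2),
               ignore_attr = TRUE)
  # the 0.5 segment passes through (0.5, 0.25, 0.25)
  seg5 <- isoportion_line("P", 0.5)
  mid <- (as.matrix(seg5[1, c("P", "C", "L")]) +
            as.matrix(seg5[2, c("P", "C", "L")])) / 2
  expect_equal(as.numeric(mid), c(0.5, 0.25, 0.25))
  banded <- isoportion_line("P", 0.17, band = 0.04)
  expect_equal(sort(unique(banded$level)), c(0.13, 0.17, 0.21))
  expect_error(isoportion_line("P", 1), "strictly")
})

test_that("1:1 isoproportion lines radiate from the opposite corner", {
  seg <- isoproportion_line(c("P", "L"))
  expect_equal(as.numeric(seg[1, c("P", "C", "L")]), c(0, 1, 0))
  expect_equal(as.numeric(seg[2, c("P", "C", "L")]), c(0.5, 0, 0.5))
  # the barycentre lies on every 1:1 line: check collinearity in the EMT
  xy <- emt_coords(dplyr::bind_rows(seg, tibble::tibble(P = 1/3, C = 1/3, L = 1/3)))
  cross <- (xy$x[2] - xy$x[1]) * (xy$y[3] - xy$y[1]) -
    (xy$y[2] - xy$y[1]) * (xy$x[3] - xy$x[1])
  expect_equal(cross, 0, tolerance = 1e-12)
  expect_error(isoproportion_line(c("P", "P")), "distinct")
})

test_that("PCA axis curves are geodesics: straight in ilr coordinates", {
  x <- random_comp_set(25, seed = 19)
  p <- comp_pca(x)
  crv <- pca_axis_curve(p, 1, n_points = 33)
  expect_valid_composition(crv)
  expect_equal(as.numeric(crv[17, c("P", "C", "L")]),
               as.numeric(p$center[1, ]), tolerance = 1e-9) # t = 0 at centre
  v <- as.matrix(comp_ilr(crv[c("P", "C", "L")])[c("ilr1", "ilr2")])
  # collinearity: all points on one line through the centre
  dv <- sweep(v, 2, v[17, ], "-")
  cross <- dv[, 1] * dv[33, 2] - dv[, 2] * dv[33, 1]
  expect_equal(max(abs(cross)), 0, tolerance = 1e-9)
  # the two component directions are orthogonal in ilr space
  d1 <- as.numeric(p$loadings[, 1] %*% t(ilr_basis(p$parts)))
  d2 <- as.numeric(p$loadings[, 2] %*% t(ilr_basis(p$parts)))
  expect_equal(sum(d1 * d2), 0, tolerance = 1e-9)
  expect_error(pca_axis_curve(p, 1, span = c(-Inf, Inf)), "finite")
})

test_that("EMT and RMT scenes build deterministically and render to SVG", {
  set.seed(4)
  x <- dplyr::mutate(sample_logistic_normal(19, ref_mean(), ref_cov()),
                     group = rep(c("natural", "anthropogenic"), length.out = 19))
  p <- plot_emt(x, colour = "group", sigma = c(2, 3), conf = 0.90,
                target = intake_target(), iso_pairs = list(c("P", "L")),
                pca = comp_pca(x))
  expect_s3_class(p, "ggplot")
  b1 <- ggplot2::ggplot_build(p)$data
  b2 <- ggplot2::ggplot_build(plot_emt(x, colour = "group", sigma = c(2, 3),
                                       conf = 0.90, target = intake_target(),
                                       iso_pairs = list(c("P", "L")),
                                       pca = comp_pca(x)))$data
  expect_identical(b1, b2) # same scene + style -> identical layer data
  p2 <- plot_rmt(x)
  expect_s3_class(p2, "ggplot")
  path <- withr::local_tempfile(fileext = ".svg")
  render_svg(p, path)
  expect_true(file.exists(path) && file.size(path) > 1000)
})
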