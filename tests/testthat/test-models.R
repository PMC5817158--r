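test_that("intercept-only compositional LM fits the geometric mean", {
  x <- random_comp_set(20, seed = 42)
  fit <- comp_lm(x, ~ 1)
  ag <- augment(fit)
  gm <- comp_mean(x)
  expect_equal(ag$.fitted_P, rep(gm$P, 20), tolerance = 1e-9)
  expect_equal(ag$.fitted_C, rep(gm$C, 20), tolerance = 1e-9)
  # residual clr rows sum to zero (ilr residuals mapped through the basis)
  res_clr <- stats::residuals(fit$fit) %*% fit$basis
  expect_equal(max(abs(rowSums(res_clr))), 0, tolerance = 1e-12)
})

test_that("group means from a factor fit equal per-group geometric means", {
  set.seed(5)
  x <- dplyr::bind_rows(
    dplyr::mutate(sample_logistic_normal(12, ref_mean(), ref_cov()), g = "a"),
    dplyr::mutate(sample_logistic_normal(15, tibble::tibble(P = 0.2, C = 0.5, L = 0.3),
                                         ref_cov()), g = "b")
  )
  fit <- comp_lm(x, ~ g)
  means <- dplyr::arrange(comp_lm_means(fit), g)
  for (grp in c("a", "b")) {
    gm <- comp_mean(x[x$g == grp, c("P", "C", "L")])
    expect_equal(as.numeric(means[means$g == grp, c("P", "C", "L")]),
                 as.numeric(gm[1, ]), tolerance = 1e-9)
  }
})

test_that("two-group parameter recovery at n = 200 per group", {
  mu_a <- tibble::tibble(P = 0.45, C = 0.22, L = 0.33)
  mu_b <- tibble::tibble(P = 0.25, C = 0.45, L = 0.30)
  set.seed(99)
  x <- dplyr::bind_rows(
    dplyr::mutate(sample_logistic_normal(200, mu_a, ref_cov()), g = "a"),
    dplyr::mutate(sample_logistic_normal(200, mu_b, ref_cov()), g = "b")
  )
  means <- comp_lm_means(comp_lm(x, ~ g))
  expect_lt(max(abs(as.numeric(means[means$g == "a", c("P", "C", "L")]) -
                      as.numeric(mu_a[1, ]))), 0.01)
  expect_lt(max(abs(as.numeric(means[means$g == "b", c("P", "C", "L")]) -
                      as.numeric(mu_b[1, ]))), 0.01)
})

test_that("perfect-fit data leave zero residuals and winter rows are dropped", {
  grp <- rep(c("a", "b"), each = 5)
  comp <- ifelse(grp == "a", 0.5, 0.2)
  x <- tibble::tibble(P = comp, C = 0.3, L = 1 - comp - 0.3, g = grp)
  fit <- comp_lm(x, ~ g)
  expect_lt(max(abs(stats::residuals(fit$fit))), 1e-12)
  xw <- dplyr::bind_rows(
    tibble::tibble(P = 0.4, C = 0.3, L = 0.3, g = "a", season = "spring"),
    dplyr::mutate(x, season = "summer")
  )
  expect_message(fitw <- comp_lm(dplyr::bind_rows(
    xw, tibble::tibble(P = 0.1, C = 0.8, L = 0.1, g = "a", season = "winter")
  ), ~ g), "winter")
  expect_equal(nrow(fitw$data), nrow(xw))
})

test_that("multivariate ANOVA is basis invariant and detects separation", {
  set.seed(17)
  x <- dplyr::bind_rows(
    dplyr::mutate(sample_logistic_normal(20, ref_mean(), ref_cov()), g = "a"),
    dplyr::mutate(sample_logistic_normal(20, ref_mean(), ref_cov()), g = "b")
  )
  B1 <- ilr_basis(c("P", "C", "L"))
  rot <- matrix(c(cos(1), -sin(1), sin(1), cos(1)), 2)
  B2 <- rot %*% B1
  a1 <- comp_anova(comp_lm(x, ~ g, basis = B1), "g")
  a2 <- comp_anova(comp_lm(x, ~ g, basis = B2), "g")
  expect_equal(a1$p_value, a2$p_value, tolerance = 1e-9)
  expect_equal(a1$value, a2$value, tolerance = 1e-9)
  # strong separation: means ~3 Aitchison units apart
  far <- comp_ilr_inv(tibble::tibble(ilr1 = 3 / sqrt(2), ilr2 = 3 / sqrt(2)))
  y <- dplyr::bind_rows(
    dplyr::mutate(sample_logistic_normal(20, ref_mean(), ref_cov()), g = "a"),
    dplyr::mutate(sample_logistic_normal(20, far, ref_cov()), g = "b")
  )
  expect_lt(comp_anova(comp_lm(y, ~ g), "g")$p_value, 0.001)
  # Pillai option agrees on direction
  expect_lt(comp_anova(comp_lm(y, ~ g), "g", statistic = "Pillai")$p_value, 0.001)
  expect_error(comp_anova(comp_lm(x, ~ g), "season"), "not in the model")
})

test_that("logit LMs report the ordered linear trend per macronutrient", {
  expect_equal(stats::qlogis(0.5), 0)
  # season-constant data -> zero linear contrast
  x <- tibble::tibble(
    P = rep(0.4, 9), C = rep(0.35, 9), L = rep(0.25, 9),
    season = rep(c("spring", "summer", "autumn"), each = 3)
  )
  # season-constant data: stats::summary.lm warns about the perfect fit
  suppressWarnings(out <- logit_lm(x, levels = c("spring", "summer", "autumn")))
  expect_equal(out$linear_estimate, rep(0, 3), tolerance = 1e-12)
  # monotone protein decline -> negative significant linear contrast,
  # agreeing with the compositional ANOVA
  set.seed(23)
  mk <- function(p, s) dplyr::mutate(
    sample_logistic_normal(15, tibble::tibble(P = p, C = (1 - p) * 0.45,
                                              L = (1 - p) * 0.55),
                           ref_cov(0.02)),
    season = s
  )
  y <- dplyr::bind_rows(mk(0.45, "spring"), mk(0.33, "summer"), mk(0.20, "autumn"))
  res <- logit_lm(y, levels = c("spring", "summer", "autumn"))
  pr <- res[res$part == "P", ]
  expect_lt(pr$linear_estimate, 0)
  expect_lt(pr$p_value, 0.01)
  y$season <- factor(y$season, levels = c("spring", "summer", "autumn"))
  expect_lt(comp_anova(comp_lm(y, ~ season), "season")$p_value, 0.01)
  expect_error(logit_lm(tibble::tibble(P = 1, C = 0, L = 0, season = "spring")),
               "strictly")
})

test_that("stacked-coordinate Cook's distance flags the constructed outlier", {
  # duplicated balanced data: identical influence everywhere
  x <- tibble::tibble(P = rep(c(0.4, 0.3), 4), C = rep(c(0.3, 0.4), 4),
                      L = 0.3)
  d <- comp_cooks_distance(comp_lm(x, ~ 1))
  expect_equal(max(d$cooks_d) - min(d$cooks_d), 0, tolerance = 1e-9)
  # a far outlier appended to a tight cluster attains the maximum
  set.seed(3)
  tight <- sample_logistic_normal(15, ref_mean(), ref_cov(0.005))
  out <- dplyr::bind_rows(tight, tibble::tibble(P = 0.90, C = 0.02, L = 0.08))
  out$population_id <- seq_len(16)
  fit <- comp_lm(out, ~ 1)
  cd <- comp_cooks_distance(fit)
  expect_equal(which.max(cd$cooks_d), 16)
  # sensitivity refit without it moves the mean back toward the cluster
  refit <- comp_lm_drop(fit, rows = which.max(cd$cooks_d))
  gm_all <- comp_mean(out[c("P", "C", "L")])
  gm_ref <- comp_mean(refit$data[c("P", "C", "L")])
  gm_cluster <- comp_mean(tight)
  expect_lt(aitchison_dist(gm_ref, gm_cluster), aitchison_dist(gm_all, gm_cluster))
  # drop by population id
  expect_equal(nrow(comp_lm_drop(fit, population = 16)$data), 15)
})

test_that("intake-target comparison classifies by the protein band", {
  t <- intake_target()
  x <- tibble::tibble(
    P = c(0.17, 0.208, 0.493, 0.10),
    C = c(0.40, 0.474, 0.159, 0.60),
    L = c(0.43, 0.318, 0.348, 0.30)
  )
  out <- compare_to_target(x, t)
  expect_equal(as.character(out$target_class),
               c("within", "within", "above", "below"))
  expect_equal(out$protein_gap, c(0, 0.038, 0.323, -0.07), tolerance = 1e-9)
  expect_error(intake_target(0.02, 0.04), "strictly inside")
})
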