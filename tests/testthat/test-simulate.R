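test_that("logistic-normal sampling is centred, degenerate at zero spread, seeded", {
  mu <- ref_mean()
  zero <- sample_logistic_normal(5, mu, matrix(0, 2, 2), seed = 1)
  expect_equal(as.matrix(zero), matrix(as.numeric(mu), 5, 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
  a <- sample_logistic_normal(50, mu, ref_cov(), seed = 10)
  b <- sample_logistic_normal(50, mu, ref_cov(), seed = 10)
  expect_identical(a, b)
  expect_error(sample_logistic_normal(5, mu, matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("large-sample geometric mean recovers the generating centre", {
  mu <- tibble::tibble(P = 0.30, C = 0.42, L = 0.28)
  x <- sample_logistic_normal(10000, mu, variation_to_ilr_cov(bear_variation_reference),
                              seed = 202)
  gm <- comp_mean(x)
  expect_lt(max(abs(as.numeric(gm[1, ]) - as.numeric(mu[1, ]))), 0.005)
})

test_that("the default covariance reproduces the reference variation structure", {
  Sigma <- variation_to_ilr_cov(bear_variation_reference)
  expect_true(all(eigen(Sigma, symmetric = TRUE)$values > 0))
  x <- sample_logistic_normal(20000, ref_mean(), Sigma, seed = 55)
  vm <- variation_matrix(x)
  expect_equal(vm["P", "C"], 0.700, tolerance = 0.05)
  expect_equal(vm["P", "L"], 0.197, tolerance = 0.05)
  expect_equal(vm["C", "L"], 0.577, tolerance = 0.05)
  # carbohydrate log-ratios are the most variable, as in the reference
  expect_equal(which.max(colSums(vm)), c(C = 2))
})

test_that("synthetic studies are reproducible and carry consistent truth", {
  cfg <- scenario_config(n_populations = 6)
  s1 <- simulate_study(cfg, seed = 31)
  s2 <- simulate_study(cfg, seed = 31)
  expect_identical(s1$records, s2$records)
  expect_equal(nrow(s1$truth), 6 * 3)
  expect_valid_composition(s1$truth)
  # %Vol sums to 100 within each population-season
  tot <- dplyr::summarise(dplyr::group_by(s1$records, population_id, season),
                          t = sum(pct_vol), .groups = "drop")
  expect_equal(tot$t, rep(100, nrow(tot)), tolerance = 1e-9)
})

test_that("noise-free studies invert exactly through the estimation pipeline", {
  cfg <- scenario_config(n_populations = 5, dirichlet_conc = Inf)
  s <- simulate_study(cfg, seed = 8)
  est <- estimate_diets(s$records, s$cf_table, s$food_table)
  joined <- dplyr::inner_join(est, s$truth, by = c("population_id", "season"),
                              suffix = c("_est", "_true"))
  expect_equal(nrow(joined), 15)
  expect_lt(max(abs(joined$P_est - joined$P_true),
                abs(joined$C_est - joined$C_true),
                abs(joined$L_est - joined$L_true)), 1e-9)
})

test_that("reconstruction error shrinks as Dirichlet concentration grows", {
  err <- vapply(c(30, 3000), function(conc) {
    cfg <- scenario_config(n_populations = 8, dirichlet_conc = conc)
    s <- simulate_study(cfg, seed = 77)
    est <- estimate_diets(s$records, s$cf_table, s$food_table)
    joined <- dplyr::inner_join(est, s$truth, by = c("population_id", "season"),
                                suffix = c("_est", "_true"))
    mean(aitchison_dist(
      dplyr::rename(joined[c("P_est", "C_est", "L_est")],
                    P = P_est, C = C_est, L = L_est),
      dplyr::rename(joined[c("P_true", "C_true", "L_true")],
                    P = P_true, C = C_true, L = L_true)
    ))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("scenario presets encode the intended group structure", {
  null_cfg <- scenario_config("null")
  m <- null_cfg$group_season_means
  nat <- m[m$group == "natural", c("season", "P", "C", "L")]
  ant <- m[m$group == "anthropogenic", c("season", "P", "C", "L")]
  expect_equal(dplyr::arrange(nat, season), dplyr::arrange(ant, season))
  trend <- scenario_config("seasonal-trend")
  expect_equal(trend$p_anthropogenic, 0)
  tm <- trend$group_season_means
  expect_lt(tm$P[tm$season == "autumn"], tm$P[tm$season == "spring"])
  expect_gt(tm$C[tm$season == "autumn"], tm$C[tm$season == "spring"])
  default_cfg <- scenario_config()
  expect_equal(sort(unique(default_cfg$group_season_means$group)),
               c("anthropogenic", "natural"))
})
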