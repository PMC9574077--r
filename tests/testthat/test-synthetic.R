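test_that("generation is fully deterministic under a fixed seed", {
  c1 <- synthetic_dea_config(n_units = 12, years = 2009:2011, seed = 5)
  g1 <- generate_dea_panel(c1)
  g2 <- generate_dea_panel(c1)
  expect_identical(g1, g2)
  g3 <- generate_dea_panel(synthetic_dea_config(n_units = 12,
                                                years = 2009:2011, seed = 6))
  expect_false(identical(g1$panel$I1, g3$panel$I1))
  w <- build_weights(china_adjacency(), china_provinces())
  s1 <- generate_sdm_panel(synthetic_sdm_config(seed = 8), w)
  s2 <- generate_sdm_panel(synthetic_sdm_config(seed = 8), w)
  expect_identical(s1, s2)
})

test_that("planted radial inefficiency is the exact LP stage-1 truth", {
  g <- generate_dea_panel(synthetic_dea_config(n_units = 10, years = 2009,
                                               n_frontier = 3, seed = 7))
  p <- positivize_indicators(g$panel)
  sc <- suppressWarnings(run_dea_year(p, 2009))
  cmp <- merge(as.data.frame(sc), g$truth, by = c("unit", "year"))
  expect_lt(max(abs(cmp$stage1 - cmp$stage1_true)), 1e-6)
  expect_lt(max(abs(cmp$stage2 - cmp$stage2_true)), 1e-6)
  expect_lt(max(abs(cmp$overall - cmp$overall_true)), 1e-6)
  # frontier units are efficient in every dimension
  fr <- cmp[cmp$frontier, ]
  expect_equal(fr$overall, rep(1, nrow(fr)), tolerance = 1e-9)
})

test_that("an all-frontier configuration yields all-efficient units", {
  g <- generate_dea_panel(synthetic_dea_config(n_units = 6, years = 2009,
                                               n_frontier = 6, seed = 3))
  expect_true(all(g$truth$stage1_true == 1))
  p <- positivize_indicators(g$panel)
  sc <- run_dea_year(p, 2009)
  expect_equal(sc$overall, rep(1, 6), tolerance = 1e-9)
})

test_that("generated indicators live in realistic magnitude ranges", {
  # within one order of magnitude of the published min/max per indicator
  ref <- list(I1 = c(199.8, 3944.5), M1 = c(0.20, 2.18), M2 = c(2.74, 12.62),
              M3 = c(2.60, 7.99), F1 = c(959, 89200), F2 = c(48.3, 100.2),
              F3 = c(0.0015, 0.0124), F4 = c(0.0043, 0.9091),
              F5 = c(0.416, 5.556))
  g <- generate_dea_panel(synthetic_dea_config(seed = 17))
  for (cl in names(ref)) {
    expect_gte(min(g$panel[[cl]]), ref[[cl]][1] / 10)
    expect_lte(max(g$panel[[cl]]), ref[[cl]][2] * 10)
  }
})

test_that("the SDM generator honours its closed-form limits", {
  w <- build_weights(china_adjacency(), china_provinces())
  # sigma = 0, effects 0, eta = 0, rho = 0: y = X beta exactly
  cfg <- synthetic_sdm_config(rho = 0, eta = rep(0, 5), sigma = 0,
                              unit_sd = 0, time_sd = 0, seed = 2)
  g <- generate_sdm_panel(cfg, w)
  d <- build_sdm_data(g$y, g$covariates, w)
  expect_equal(g$y$overall, as.vector(d$X %*% cfg$beta), tolerance = 1e-10)
  # recovery at the default spatial strength
  cfg2 <- synthetic_sdm_config(n_units = 49, T = 12, rho = 0.4, seed = 11)
  w49 <- grid_weights(7, 7)
  g2 <- generate_sdm_panel(cfg2, w49)
  fit <- fit_sdm(build_sdm_data(g2$y, g2$covariates, w49))
  expect_gt(fit$rho, 0.3)
  expect_lt(fit$rho, 0.5)
})

test_that("the packaged province contiguity fixture is coherent", {
  adj <- china_adjacency()
  prov <- china_provinces()
  expect_equal(length(prov), 31)
  expect_true(all(c(adj$from, adj$to) %in% prov))
  w <- build_weights(adj, prov, standardize = FALSE)
  expect_true(isSymmetric(w$W))
  expect_true(all(rowSums(w$W) >= 1))          # no isolated unit
  expect_equal(w$W["Hainan", "Guangdong"], 1)  # declared island link
  expect_equal(sum(w$W["Hainan", ]), 1)
})

test_that("spatially clustered generation produces autocorrelated efficiency", {
  w <- build_weights(china_adjacency(), china_provinces())
  g <- generate_dea_panel(synthetic_dea_config(weights = w, seed = 1))
  p <- positivize_indicators(g$panel)
  sc <- suppressWarnings(run_dea_year(p, 2009))
  x <- sc$overall[match(w$units, sc$unit)]
  res <- moran_inference(x, w, n_permutations = 999, seed = 1)
  expect_gt(res$I, 0)
  expect_lte(res$p_value, 0.05)
})
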