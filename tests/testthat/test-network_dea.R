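cfg <- dea_config()

test_that("single-dimension CCR reduces to ratio-to-best-ratio", {
  X <- matrix(c(1, 1)); Y <- matrix(c(4, 1))
  expect_equal(ccr_efficiency(X, Y, 1, cfg)$score, 1, tolerance = 1e-9)
  expect_equal(ccr_efficiency(X, Y, 2, cfg)$score, 0.25, tolerance = 1e-9)
  # a unit that weakly dominates every other ratio is on the frontier
  set.seed(4)
  X <- matrix(runif(5, 1, 2)); Y <- X * c(2, 1, 1.5, 1.2, 0.7)
  expect_equal(ccr_efficiency(X, Y, 1, cfg)$score, 1, tolerance = 1e-9)
})

test_that("the one-dimensional chain collapses to ratios and decomposes as stage products", {
  inst <- dea_instance(X = matrix(c(1, 1, 2)), Z = matrix(c(2, 1, 2)),
                       Y = matrix(c(4, 1, 2)), units = c("A", "B", "C"))
  e <- vapply(1:3, function(k) relational_overall(inst, k, cfg)$score,
              numeric(1))
  expect_equal(e, c(1, 0.25, 0.25), tolerance = 1e-9)
  dB <- decompose_stages(inst, 2, e[2], cfg)
  expect_equal(dB$stage1, 0.5, tolerance = 1e-9)
  expect_equal(dB$stage2, 0.5, tolerance = 1e-9)
  dA <- decompose_stages(inst, 1, e[1], cfg)
  expect_equal(c(dA$stage1, dA$stage2), c(1, 1), tolerance = 1e-9)
})

test_that("relational efficiency is nested below the independent CCR score", {
  set.seed(11)
  for (i in 1:8) {
    inst <- random_instance(sample(3:6, 1), 1, 2, 2)
    for (k in seq_along(inst$units)) {
      rel <- relational_overall(inst, k, cfg)$score
      ind <- ccr_efficiency(inst$X, inst$Y, k, cfg)$score
      expect_lte(rel, ind + 1e-8)
    }
  }
})

test_that("efficiencies are invariant to rescaling any single column", {
  set.seed(21)
  inst <- random_instance(6, 1, 3, 2)
  base <- vapply(1:6, function(k) relational_overall(inst, k, cfg)$score,
                 numeric(1))
  for (scl in list(list("X", 1, 7), list("Z", 2, 0.001), list("Y", 1, 5e4))) {
    inst2 <- inst
    inst2[[scl[[1]]]][, scl[[2]]] <- inst2[[scl[[1]]]][, scl[[2]]] * scl[[3]]
    inst2 <- dea_instance(inst2$X, inst2$Z, inst2$Y, inst2$units)
    sc <- vapply(1:6, function(k) relational_overall(inst2, k, cfg)$score,
                 numeric(1))
    expect_equal(sc, base, tolerance = 1e-8)
  }
})

test_that("weakly improving a unit never lowers its efficiency", {
  set.seed(31)
  for (i in 1:5) {
    inst <- random_instance(5, 1, 2, 2)
    k <- sample(5, 1)
    before <- relational_overall(inst, k, cfg)$score
    inst$Y[k, ] <- inst$Y[k, ] * 1.2           # more final output
    inst <- dea_instance(inst$X, inst$Z, inst$Y, inst$units)
    expect_gte(relational_overall(inst, k, cfg)$score, before - 1e-8)
    inst$X[k, ] <- inst$X[k, ] * 0.8           # less input
    inst <- dea_instance(inst$X, inst$Z, inst$Y, inst$units)
    expect_gte(relational_overall(inst, k, cfg)$score, before - 1e-8)
  }
})

test_that("every cross-section has nonempty stage frontiers and bounded scores", {
  set.seed(41)
  for (i in 1:6) {
    n <- sample(4:7, 1)
    inst <- random_instance(n, 1, 2, 2)
    s1 <- s2 <- numeric(n)
    for (k in 1:n) {
      e <- relational_overall(inst, k, cfg)
      d <- decompose_stages(inst, k, e$score, cfg)
      expect_gt(e$score, 0)
      expect_lte(e$score, 1 + 1e-9)
      expect_lte(abs(e$score - d$stage1 * d$stage2), 1e-6)
      s1[k] <- d$stage1; s2[k] <- d$stage2
    }
    expect_gte(max(s1), 1 - 1e-7)
    expect_gte(max(s2), 1 - 1e-7)
  }
})

test_that("both decomposition priorities satisfy the product identity and order sensibly", {
  set.seed(51)
  cfg2 <- dea_config(priority = "stage2_first")
  inst <- random_instance(6, 1, 2, 2)
  for (k in 1:6) {
    e <- relational_overall(inst, k, cfg)$score
    d1 <- decompose_stages(inst, k, e, cfg)
    d2 <- decompose_stages(inst, k, e, cfg2)
    expect_lte(abs(e - d1$stage1 * d1$stage2), 1e-6)
    expect_lte(abs(e - d2$stage1 * d2$stage2), 1e-6)
    # stage1-first maximizes stage 1, so it cannot be below the alternative
    expect_gte(d1$stage1, d2$stage1 - 1e-7)
  }
})

test_that("run_dea_year wires the indicator system into the instance correctly", {
  g <- generate_dea_panel(synthetic_dea_config(n_units = 8, years = 2009,
                                               n_frontier = 3, seed = 13))
  expect_error(run_dea_year(g$panel, 2009), "must be positivized")
  p <- positivize_indicators(g$panel)
  expect_error(run_dea_year(p, 1999), "not present")
  sc <- suppressWarnings(run_dea_year(p, 2009))
  expect_s3_class(sc, "dea_scores")
  expect_setequal(sc$unit, g$panel$unit[g$panel$year == 2009])
  # identical units are all efficient
  one <- as.data.frame(p[p$year == 2009, ])
  clone <- do.call(rbind, replicate(4, one[1, ], simplify = FALSE))
  clone$unit <- letters[1:4]
  pc <- as_indicator_panel(clone, positivized = TRUE)
  scc <- run_dea_year(pc, 2009)
  expect_equal(scc$overall, rep(1, 4), tolerance = 1e-9)
  # doubling the single input of a stage-1-efficient unit halves its stage-1 score
  two <- one[1:2, ]
  two$unit <- c("a", "b")
  two[2, -(1:2)] <- two[1, -(1:2)]
  two$I1[2] <- two$I1[1] * 2
  pt <- as_indicator_panel(two, positivized = TRUE)
  sct <- suppressWarnings(run_dea_year(pt, 2009))
  expect_equal(sct$stage1[sct$unit == "b"],
               sct$stage1[sct$unit == "a"] / 2, tolerance = 1e-8)
})

test_that("LP efficiencies match the brute-force ratio-form oracle on small instances", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(2:6, 1); a <- sample(1:2, 1); b <- sample(1:2, 1)
    X <- matrix(runif(n * a, 0.5, 2), n)
    Y <- matrix(runif(n * b, 0.5, 2), n)
    k <- sample(n, 1)
    expect_equal(ccr_efficiency(X, Y, k, cfg)$score, ccr_oracle(X, Y, k),
                 tolerance = 1e-3)
  }
})

test_that("relational scores match the multistart nonlinear oracle", {
  set.seed(71)
  inst <- random_instance(6, 1, 2, 2)
  for (k in 1:6) {
    expect_equal(relational_overall(inst, k, cfg)$score,
                 relational_oracle(inst, k, n_starts = 100, seed = 100 + k),
                 tolerance = 1e-4)
  }
})
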