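w31 <- build_weights(china_adjacency(), china_provinces())

make_sdm <- function(seed, ...) {
  cfg <- synthetic_sdm_config(seed = seed, ...)
  g <- generate_sdm_panel(cfg, w31)
  list(cfg = cfg, g = g, data = build_sdm_data(g$y, g$covariates, w31))
}

test_that("with rho = eta = 0 the fit collapses to the within OLS estimator", {
  s <- make_sdm(3, rho = 0, eta = rep(0, 5), sigma = 0.05)
  fit <- fit_sdm(s$data, model = "slm")
  yt <- healthdea:::.demean(s$data$y, s$data$n, s$data$T, "twoways")
  Xt <- healthdea:::.demean(s$data$X, s$data$n, s$data$T, "twoways")
  ols <- qr.coef(qr(Xt), yt)
  # rho estimate near zero, beta near within-OLS and near truth
  expect_lt(abs(fit$rho), 0.1)
  fit0 <- suppressWarnings(
    fit_sdm(s$data, model = "slm", rho_interval = c(-1e-9, 1e-9)))
  expect_equal(unname(fit0$beta), unname(ols), tolerance = 1e-6)
  se <- sqrt(diag(fit$vcov))[1:5]
  expect_true(all(abs(fit$beta - s$cfg$beta) < 4 * se))
})

test_that("the noiseless limit recovers the coefficients essentially exactly", {
  s <- make_sdm(5, rho = 0, eta = rep(0, 5), sigma = 0, unit_sd = 0,
                time_sd = 0)
  fit <- suppressWarnings(
    fit_sdm(s$data, model = "slm", rho_interval = c(-1e-9, 1e-9)))
  expect_equal(unname(fit$beta), s$cfg$beta, tolerance = 1e-8)
})

test_that("the concentrated likelihood at the optimum dominates rho = 0", {
  s <- make_sdm(7, rho = 0.4)
  fit <- fit_sdm(s$data)
  fit0 <- suppressWarnings(fit_sdm(s$data, rho_interval = c(-1e-9, 1e-9)))
  expect_gte(fit$loglik, fit0$loglik)
  expect_gt(fit$rho, 0.15)
})

test_that("within transformation is idempotent", {
  set.seed(2)
  v <- rnorm(31 * 12)
  d1 <- healthdea:::.demean(v, 31, 12, "twoways")
  expect_equal(healthdea:::.demean(d1, 31, 12, "twoways"), d1,
               tolerance = 1e-12)
})

test_that("the analytic information-matrix SEs agree with the numerical Hessian", {
  s <- make_sdm(9, rho = 0.3)
  fit <- fit_sdm(s$data, sigma2_correct = FALSE)
  d <- s$data; n <- d$n; tt <- d$T; N <- n * tt
  W <- d$W
  wx <- healthdea:::.wlag(d$X, W, n, tt)
  Xf <- cbind(d$X, wx)
  yt <- healthdea:::.demean(d$y, n, tt, "twoways")
  wyt <- healthdea:::.demean(healthdea:::.wlag(d$y, W, n, tt), n, tt, "twoways")
  Xt <- healthdea:::.demean(Xf, n, tt, "twoways")
  lam <- eigen(W, only.values = TRUE)$values
  negll <- function(th) {
    delta <- th[1:10]; rho <- th[11]; s2 <- th[12]
    e <- yt - rho * wyt - as.vector(Xt %*% delta)
    -(-(N / 2) * log(2 * pi * s2) + tt * sum(Re(log(1 - rho * lam))) -
        sum(e^2) / (2 * s2))
  }
  th_hat <- c(fit$beta, fit$eta, fit$rho, fit$sigma2)
  H <- stats::optimHess(th_hat, negll)
  se_num <- sqrt(diag(solve(H)))
  se_ana <- sqrt(diag(fit$vcov))
  expect_equal(unname(se_ana), unname(se_num), tolerance = 0.1)
})

test_that("effect decomposition is additive and collapses correctly at rho = 0", {
  s <- make_sdm(13, rho = 0.35)
  fit <- fit_sdm(s$data)
  eff <- effects_decomposition(fit, n_draws = 300, seed = 4)
  expect_equal(eff$direct + eff$indirect, eff$total, tolerance = 1e-12)
  # rho = 0 closed form: direct = beta, indirect = eta (row-standardized W)
  fit0 <- fit
  fit0$rho <- 0
  pt <- healthdea:::.effects_point(0, fit0$beta, fit0$eta, fit0$W)
  expect_equal(pt$direct, unname(fit0$beta), tolerance = 1e-12)
  expect_equal(pt$indirect, unname(fit0$eta), tolerance = 1e-12)
  # draws reproducible under the same seed
  eff2 <- effects_decomposition(fit, n_draws = 300, seed = 4)
  expect_identical(eff$se_direct, eff2$se_direct)
})

test_that("LM statistics are nonnegative and favour the true alternative", {
  s <- make_sdm(17, rho = 0.6)
  lt <- lm_tests(s$data)
  expect_true(all(lt$statistic >= 0))
  expect_equal(lt$df, rep(1, 4))
  expect_gt(lt$statistic[lt$test == "lm_lag"], qchisq(0.95, 1))
})

test_that("LR/Wald tests have k degrees of freedom and reject under an SDM truth", {
  s <- make_sdm(19, rho = 0.4)
  fit <- fit_sdm(s$data)
  tw <- lr_wald_tests(fit, s$data)
  expect_equal(tw$df, rep(5, 4))
  expect_true(all(tw$statistic >= 0))
  expect_true(all(tw$p_value < 0.01))
})

test_that("Hausman statistic is zero for identical estimates and detects correlated effects", {
  V <- diag(5) * 0.01
  h0 <- hausman_test(1:5, V, 1:5, V * 0.5)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$df, 5)
  # exogenous effects: FE and RE agree
  s <- make_sdm(23, rho = 0)
  expect_gt(panel_hausman(s$data)$p_value, 0.01)
  # unit effects correlated (0.7) with the first regressor: strong rejection
  set.seed(31)
  rej <- 0
  for (r in 1:60) {
    cfg <- synthetic_sdm_config(rho = 0, eta = rep(0, 5), sigma = 0.05,
                                unit_sd = 0, cov_unit_sdlog = 0.5,
                                seed = 7000 + r)
    g <- generate_sdm_panel(cfg, w31)
    d <- build_sdm_data(g$y, g$covariates, w31)
    xbar <- rowMeans(matrix(d$X[, 1], d$n, d$T))
    z <- scale(xbar)[, 1]
    mu <- 0.25 * (0.7 * z + sqrt(1 - 0.49) * rnorm(d$n))
    d$y <- d$y + rep(mu, d$T)
    rej <- rej + (panel_hausman(d)$p_value < 0.05)
  }
  expect_gte(rej / 60, 0.8)
})

test_that("coefficient signs at the provincial scale are recovered", {
  # magnitudes of the published provincial model; signs of the three
  # significant covariates (1, 2, 5) must come back
  set.seed(91)
  ok_b <- matrix(NA, 40, 3); ok_e <- matrix(NA, 40, 3)
  for (r in 1:40) {
    cfg <- synthetic_sdm_config(rho = 0.3, seed = 9000 + r)
    g <- generate_sdm_panel(cfg, w31)
    fit <- fit_sdm(build_sdm_data(g$y, g$covariates, w31))
    ok_b[r, ] <- sign(fit$beta[c(1, 2, 5)]) == sign(cfg$beta[c(1, 2, 5)])
    ok_e[r, ] <- sign(fit$eta[c(1, 2, 5)]) == sign(cfg$eta[c(1, 2, 5)])
  }
  expect_gte(mean(ok_b), 0.9)
  expect_gte(mean(ok_e), 0.9)
})
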