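# Two-way fixed-effects spatial Durbin panel model (SDM), estimated by
# concentrated maximum likelihood, with the LM/LR/Wald/Hausman selection
# battery and LeSage-Pace direct/indirect/total effect decomposition.
#
# Model:  Y = alpha + rho W Y + X beta + W X eta + mu + v + eps
# for a balanced panel of n spatial units over T periods, W row-standardized.
# Observations are stacked time-major: period 1's n units first.

#' Assemble data for the spatial panel regressions
#'
#' Merges a per-unit-year dependent variable (typically the overall DEA
#' efficiency) with a covariate panel, optionally log-transforming the
#' covariates, and aligns both with a row-standardized weight matrix.
#'
#' @param scores data.frame with columns `unit`, `year` and the dependent
#'   variable (e.g. a `dea_scores` table).
#' @param covariates a `covariate_panel` (or data.frame in that layout).
#' @param weights a `spatial_weights` object, row-standardized, whose units
#'   cover the panel's units.
#' @param y_col name of the dependent-variable column in `scores`.
#' @param log_covariates log-transform the covariates (default `TRUE`; the
#'   dependent variable is never transformed).
#' @return object of class `sdm_data`: list with `y` (length nT), `X`
#'   (nT x k), `W`, `n`, `T`, `k`, `units`, `years`, `xnames`.
#' @export
build_sdm_data <- function(scores, covariates, weights, y_col = "overall",
                           log_covariates = TRUE) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!weights$standardized) weights <- row_standardize(weights)
  sc <- as.data.frame(scores)
  cv <- as.data.frame(covariates)
  stopifnot(y_col %in% names(sc))
  units <- weights$units
  miss <- setdiff(unique(sc$unit), units)
  if (length(miss)) {
    stop(sprintf("units absent from weight matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sc <- sc[sc$unit %in% units, c("unit", "year", y_col)]
  years <- sort(unique(sc$year))
  n <- length(units); tt <- length(years)
  key <- function(d) paste(d$unit, d$year)
  cv <- cv[match(paste(rep(units, tt), rep(years, each = n)), key(cv)), ]
  sc <- sc[match(paste(rep(units, tt), rep(years, each = n)), key(sc)), ]
  if (anyNA(sc[[y_col]]) || anyNA(cv$pgdp)) {
    stop("panel is not balanced over the weight-matrix units and score years",
         call. = FALSE)
  }
  xn <- covariate_cols()
  X <- as.matrix(cv[, xn])
  if (log_covariates) {
    X <- log(X)
    xn <- paste0("ln", xn)
  }
  colnames(X) <- xn
  if (!all(is.finite(X))) stop("covariates not finite after log transform",
                               call. = FALSE)
  structure(list(y = sc[[y_col]], X = X, W = weights$W, n = n, T = tt,
                 k = ncol(X), units = units, years = years, xnames = xn),
            class = "sdm_data")
}

# ---- internal helpers -------------------------------------------------------

# apply W within each period to a stacked vector/matrix
.wlag <- function(v, W, n, tt) {
  if (is.matrix(v)) {
    out <- v
    for (t in seq_len(tt)) {
      i <- (t - 1) * n + seq_len(n)
      out[i, ] <- W %*% v[i, , drop = FALSE]
    }
    out
  } else {
    as.vector(.wlag(matrix(v, ncol = 1), W, n, tt))
  }
}

# within transformation; effects in {"twoways","individual","time","none"}
.demean <- function(v, n, tt, effects) {
  one_col <- function(x) {
    m <- matrix(x, n, tt)
    switch(effects,
      twoways = {
        m <- m - rowMeans(m)
        m <- sweep(m, 2, colMeans(m), "-")
        as.vector(m)
      },
      individual = as.vector(m - rowMeans(m)),
      time = as.vector(sweep(m, 2, colMeans(m), "-")),
      none = x - mean(x))
  }
  if (is.matrix(v)) apply(v, 2, one_col) else one_col(v)
}

.df_effective <- function(n, tt, effects) {
  switch(effects,
    twoways = (n - 1) * (tt - 1),
    individual = n * (tt - 1),
    time = (n - 1) * tt,
    none = n * tt - 1)
}

.ldet_fun <- function(W) {
  lam <- eigen(W, only.values = TRUE)$values
  function(rho) sum(Re(log(1 - rho * lam)))
}

# ---- estimation -------------------------------------------------------------

#' Fit a spatial Durbin (or spatial lag) panel model by maximum likelihood
#'
#' Fixed effects are absorbed by the within transformation (two-way
#' demeaning by default); the spatial autoregressive parameter rho is then
#' found by maximizing the concentrated log-likelihood, whose log-Jacobian
#' term `T log|I - rho W|` is evaluated through the eigenvalues of W, with
#' the regression coefficients and error variance profiled out by least
#' squares at each rho.  The reported `sigma2` applies a degrees-of-freedom
#' correction for the demeaning (`(n-1)(T-1)` effective observations under
#' two-way effects) unless `sigma2_correct = FALSE`; the covariance matrix
#' comes from the analytic information matrix of (coefficients, rho,
#' sigma2).
#'
#' @param data an [build_sdm_data()] object.
#' @param model `"sdm"` (spatial lags of y and X, default) or `"slm"`
#'   (spatial lag of y only).
#' @param effects which fixed effects to absorb: `"twoways"` (default),
#'   `"individual"`, `"time"`, or `"none"` (grand-mean/intercept only).
#' @param sigma2_correct apply the lost-degrees-of-freedom correction to
#'   the reported error variance (default `TRUE`).
#' @param rho_interval search interval for rho; default `(-0.999, 0.999)`,
#'   valid for row-standardized W.  Hitting the boundary triggers a warning.
#' @return object of class `sdm_fit`: list with `rho`, `beta`, `eta` (NULL
#'   for `"slm"`), `sigma2`, `loglik`, `vcov` (rows/cols: coefficients,
#'   rho, sigma2), `residuals`, `fitted_no_spatial`, `effects`, `model`,
#'   plus the problem dimensions.
#' @export
fit_sdm <- function(data, model = c("sdm", "slm"),
                    effects = c("twoways", "individual", "time", "none"),
                    sigma2_correct = TRUE, rho_interval = c(-0.999, 0.999)) {
  stopifnot(inherits(data, "sdm_data"))
  model <- match.arg(model)
  effects <- match.arg(effects)
  n <- data$n; tt <- data$T; N <- n * tt
  stopifnot(tt >= 2, n >= 3)
  W <- data$W
  Xf <- if (model == "sdm") {
    wx <- .wlag(data$X, W, n, tt)
    colnames(wx) <- paste0("W.", data$xnames)
    cbind(data$X, wx)
  } else data$X
  kk <- ncol(Xf)
  yt <- .demean(data$y, n, tt, effects)
  wyt <- .demean(.wlag(data$y, W, n, tt), n, tt, effects)
  Xt <- .demean(Xf, n, tt, effects)
  qrX <- qr(Xt)
  if (qrX$rank < kk) {
    stop("regressor cross-product is singular: collinear covariates (possibly after demeaning)",
         call. = FALSE)
  }
  e0 <- qr.resid(qrX, yt)
  ed <- qr.resid(qrX, wyt)
  s00 <- sum(e0^2); s0d <- sum(e0 * ed); sdd <- sum(ed^2)
  ldet <- .ldet_fun(W)
  conc <- function(rho) {
    S <- s00 - 2 * rho * s0d + rho^2 * sdd
    -(N / 2) * (log(2 * pi) + 1 + log(S / N)) + tt * ldet(rho)
  }
  opt <- stats::optimize(conc, interval = rho_interval, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  rho <- opt$maximum
  if (min(abs(rho - rho_interval)) < 1e-4) {
    warning(sprintf("rho estimate %.4f is at the search-interval boundary; the model may be misspecified",
                    rho), call. = FALSE)
  }
  delta <- qr.coef(qrX, yt - rho * wyt)
  resid <- yt - rho * wyt - as.vector(Xt %*% delta)
  S <- sum(resid^2)
  df_eff <- .df_effective(n, tt, effects)
  sigma2 <- if (sigma2_correct) S / df_eff else S / N
  loglik <- conc(rho)

  # analytic information matrix for theta = (delta, rho, sigma2)
  nm <- c(colnames(Xf), "rho", "sigma2")
  if (sigma2 < 1e-12 * max(stats::var(yt), .Machine$double.eps)) {
    warning("residual variance is numerically zero; covariance matrix unavailable",
            call. = FALSE)
    vcov <- matrix(NA_real_, kk + 2, kk + 2, dimnames = list(nm, nm))
    k <- data$k
    return(structure(list(
      rho = rho,
      beta = stats::setNames(delta[seq_len(k)], data$xnames),
      eta = if (model == "sdm")
        stats::setNames(delta[k + seq_len(k)], paste0("W.", data$xnames))
        else NULL,
      sigma2 = sigma2, loglik = loglik, vcov = vcov, residuals = resid,
      model = model, effects = effects, sigma2_correct = sigma2_correct,
      n = n, T = tt, k = k, xnames = data$xnames, W = W,
      converged = TRUE), class = "sdm_fit"))
  }
  B <- diag(n) - rho * W
  G <- W %*% solve(B)
  p <- as.vector(Xt %*% delta)
  Gp <- .wlag(p, G, n, tt)
  XtX <- crossprod(Xt)
  info <- matrix(0, kk + 2, kk + 2)
  info[seq_len(kk), seq_len(kk)] <- XtX / sigma2
  info[seq_len(kk), kk + 1] <- crossprod(Xt, Gp) / sigma2
  info[kk + 1, seq_len(kk)] <- info[seq_len(kk), kk + 1]
  trG <- sum(diag(G))
  info[kk + 1, kk + 1] <- tt * (sum(G * t(G)) + sum(G * G)) +
    sum(Gp^2) / sigma2
  info[kk + 1, kk + 2] <- tt * trG / sigma2
  info[kk + 2, kk + 1] <- info[kk + 1, kk + 2]
  info[kk + 2, kk + 2] <- N / (2 * sigma2^2)
  vcov <- solve(info)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(nm, nm)

  k <- data$k
  structure(list(
    rho = rho,
    beta = stats::setNames(delta[seq_len(k)], data$xnames),
    eta = if (model == "sdm")
      stats::setNames(delta[k + seq_len(k)], paste0("W.", data$xnames))
      else NULL,
    sigma2 = sigma2, loglik = loglik, vcov = vcov, residuals = resid,
    model = model, effects = effects, sigma2_correct = sigma2_correct,
    n = n, T = tt, k = k, xnames = data$xnames, W = W,
    converged = TRUE), class = "sdm_fit")
}

#' Fit the spatial error panel model (for the LR battery)
#'
#' `y = X beta + u`, `u = lambda W u + eps`, fixed effects absorbed by the
#' within transformation, lambda estimated by concentrated ML with a
#' spatial Cochrane-Orcutt transform at each candidate lambda.
#'
#' @inheritParams fit_sdm
#' @return list of class `sem_fit` with `lambda`, `beta`, `sigma2`,
#'   `loglik`.
#' @export
fit_sem <- function(data, effects = c("twoways", "individual", "time", "none"),
                    sigma2_correct = TRUE, rho_interval = c(-0.999, 0.999)) {
  stopifnot(inherits(data, "sdm_data"))
  effects <- match.arg(effects)
  n <- data$n; tt <- data$T; N <- n * tt
  W <- data$W
  yt <- .demean(data$y, n, tt, effects)
  Xt <- .demean(data$X, n, tt, effects)
  wyt <- .demean(.wlag(data$y, W, n, tt), n, tt, effects)
  wXt <- .demean(.wlag(data$X, W, n, tt), n, tt, effects)
  ldet <- .ldet_fun(W)
  rss <- function(lam) {
    ys <- yt - lam * wyt
    Xs <- Xt - lam * wXt
    sum(qr.resid(qr(Xs), ys)^2)
  }
  conc <- function(lam) {
    -(N / 2) * (log(2 * pi) + 1 + log(rss(lam) / N)) + tt * ldet(lam)
  }
  opt <- stats::optimize(conc, interval = rho_interval, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  lam <- opt$maximum
  ys <- yt - lam * wyt; Xs <- Xt - lam * wXt
  beta <- qr.coef(qr(Xs), ys)
  S <- rss(lam)
  df_eff <- .df_effective(n, tt, effects)
  structure(list(lambda = lam,
                 beta = stats::setNames(beta, data$xnames),
                 sigma2 = if (sigma2_correct) S / df_eff else S / N,
                 loglik = conc(lam)),
            class = "sem_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("Spatial %s panel model (%s effects), n = %d, T = %d\n",
              toupper(x$model), x$effects, x$n, x$T))
  cf <- c(x$beta, x$eta, rho = x$rho)
  se <- sqrt(diag(x$vcov))[seq_along(cf)]
  tab <- data.frame(estimate = cf, se = se, z = cf / se,
                    p = 2 * stats::pnorm(-abs(cf / se)))
  print(round(tab, 4))
  cat(sprintf("sigma2 = %.4f, log-likelihood = %.4f\n", x$sigma2, x$loglik))
  invisible(x)
}

#' Coefficient table of a fitted spatial model
#'
#' @param fit an `sdm_fit`.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p_value`,
#'   `ci_lower`, `ci_upper` (95%).
#' @export
sdm_coef_table <- function(fit) {
  stopifnot(inherits(fit, "sdm_fit"))
  cf <- c(fit$beta, fit$eta, rho = fit$rho, sigma2 = fit$sigma2)
  se <- sqrt(diag(fit$vcov))[seq_along(cf)]
  z <- cf / se
  data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
             z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
             ci_lower = unname(cf - 1.96 * se),
             ci_upper = unname(cf + 1.96 * se))
}

# ---- effects decomposition --------------------------------------------------

#' Direct, indirect and total effects of the covariates
#'
#' For covariate r the matrix of marginal effects is
#' `S_r = (I - rho W)^(-1) (I beta_r + W eta_r)`.  The direct effect is the
#' average diagonal element, the total effect the average row sum, and the
#' indirect (spillover) effect their difference -- so
#' `direct + indirect = total` holds exactly for the point estimates.
#' Dispersion comes from draws of (coefficients, rho) from the asymptotic
#' normal of the ML estimator; z-values are the mean/sd of the simulated
#' effect distributions.
#'
#' @param fit an [fit_sdm()] result.
#' @param n_draws number of parameter draws (default 1000).
#' @param seed optional integer seed for the draws.
#' @return data.frame of class `sdm_effects`: one row per covariate with
#'   point estimates, simulation standard errors, z and p for each of
#'   direct/indirect/total.
#' @export
effects_decomposition <- function(fit, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "sdm_fit"))
  W <- fit$W
  n <- nrow(W)
  k <- fit$k
  eta <- if (is.null(fit$eta)) rep(0, k) else fit$eta
  point <- .effects_point(fit$rho, fit$beta, eta, W)
  idx <- seq_len(if (fit$model == "sdm") 2 * k else k)
  idx <- c(idx, which(colnames(fit$vcov) == "rho"))
  V <- fit$vcov[idx, idx]
  mu <- c(fit$beta, if (fit$model == "sdm") fit$eta, rho = fit$rho)
  if (!is.null(seed)) set.seed(seed)
  draws <- mvtnorm::rmvnorm(n_draws, mean = mu, sigma = V)
  arr <- array(NA_real_, c(n_draws, k, 3))
  for (d in seq_len(n_draws)) {
    b <- draws[d, seq_len(k)]
    e <- if (fit$model == "sdm") draws[d, k + seq_len(k)] else rep(0, k)
    r <- min(max(draws[d, ncol(draws)], -0.998), 0.998)
    pt <- .effects_point(r, b, e, W)
    arr[d, , ] <- as.matrix(pt[, c("direct", "indirect", "total")])
  }
  se <- apply(arr, c(2, 3), stats::sd)
  mn <- apply(arr, c(2, 3), mean)
  z <- mn / se
  out <- data.frame(
    variable = fit$xnames,
    direct = point$direct, indirect = point$indirect, total = point$total,
    se_direct = se[, 1], se_indirect = se[, 2], se_total = se[, 3],
    z_direct = z[, 1], z_indirect = z[, 2], z_total = z[, 3],
    p_direct = 2 * stats::pnorm(-abs(z[, 1])),
    p_indirect = 2 * stats::pnorm(-abs(z[, 2])),
    p_total = 2 * stats::pnorm(-abs(z[, 3])))
  structure(out, class = c("sdm_effects", "data.frame"),
            n_draws = n_draws,
            seed = if (is.null(seed)) NA_integer_ else seed)
}

.effects_point <- function(rho, beta, eta, W) {
  n <- nrow(W)
  Binv <- solve(diag(n) - rho * W)
  k <- length(beta)
  direct <- numeric(k); total <- numeric(k)
  for (r in seq_len(k)) {
    Sr <- Binv %*% (diag(n) * beta[r] + W * eta[r])
    direct[r] <- mean(diag(Sr))
    total[r] <- sum(Sr) / n
  }
  data.frame(direct = direct, indirect = total - direct, total = total)
}

# ---- specification tests ----------------------------------------------------

#' Lagrange multiplier tests for spatial lag and spatial error
#'
#' Computed on the residuals of the non-spatial two-way within regression
#' of y on X: the classic LM statistics for an omitted spatial error and an
#' omitted spatial lag, plus their robust variants (each robust to the
#' other alternative).  All are asymptotically chi-squared with 1 degree of
#' freedom.
#'
#' @param data an [build_sdm_data()] object.
#' @param effects which fixed effects the baseline regression absorbs.
#' @return data.frame with rows `lm_error`, `robust_lm_error`, `lm_lag`,
#'   `robust_lm_lag` and columns `statistic`, `df`, `p_value`.
#' @export
lm_tests <- function(data, effects = "twoways") {
  stopifnot(inherits(data, "sdm_data"))
  n <- data$n; tt <- data$T; N <- n * tt
  W <- data$W
  yt <- .demean(data$y, n, tt, effects)
  Xt <- .demean(data$X, n, tt, effects)
  qrX <- qr(Xt)
  e <- qr.resid(qrX, yt)
  sigma2 <- sum(e^2) / N
  if (sigma2 <= .Machine$double.eps) {
    stop("degenerate residual variance", call. = FALSE)
  }
  We <- .wlag(e, W, n, tt)
  Wy <- .demean(.wlag(data$y, W, n, tt), n, tt, effects)
  trw <- sum(W * t(W)) + sum(W * W)
  T1 <- tt * trw
  d_e <- sum(e * We) / sigma2
  d_y <- sum(e * Wy) / sigma2
  beta <- qr.coef(qrX, yt)
  WXb <- .demean(.wlag(as.vector(data$X %*% beta), W, n, tt), n, tt, effects)
  MWXb <- qr.resid(qrX, WXb)
  J <- (sum(MWXb^2) + T1 * sigma2) / sigma2
  lm_err <- d_e^2 / T1
  lm_lag <- d_y^2 / J
  rlm_lag <- (d_y - d_e)^2 / (J - T1)
  rlm_err <- (d_e - (T1 / J) * d_y)^2 / (T1 * (1 - T1 / J))
  stat <- c(lm_err, rlm_err, lm_lag, rlm_lag)
  data.frame(test = c("lm_error", "robust_lm_error", "lm_lag", "robust_lm_lag"),
             statistic = stat, df = 1,
             p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' LR and Wald tests for simplifying the spatial Durbin model
#'
#' Tests whether the SDM collapses to the spatial lag model (H0: eta = 0)
#' or to the spatial error model (H0: eta + rho beta = 0, the common-factor
#' restriction), by likelihood ratio against the restricted fits and by
#' Wald statistics from the SDM covariance (delta method for the
#' common-factor restriction).  All four statistics have k degrees of
#' freedom.
#'
#' @param full an `"sdm"` [fit_sdm()] result.
#' @param data the matching [build_sdm_data()] object.
#' @return data.frame with rows `lr_lag`, `wald_lag`, `lr_error`,
#'   `wald_error` and columns `statistic`, `df`, `p_value`.
#' @export
lr_wald_tests <- function(full, data) {
  stopifnot(inherits(full, "sdm_fit"), full$model == "sdm")
  k <- full$k
  slm <- fit_sdm(data, model = "slm", effects = full$effects,
                 sigma2_correct = full$sigma2_correct)
  sem <- fit_sem(data, effects = full$effects,
                 sigma2_correct = full$sigma2_correct)
  lr_lag <- 2 * (full$loglik - slm$loglik)
  lr_err <- 2 * (full$loglik - sem$loglik)
  if (lr_lag < 0 || lr_err < 0) {
    warning("restricted log-likelihood exceeds the full model's: non-convergence of one of the fits",
            call. = FALSE)
  }
  ib <- seq_len(k); ie <- k + seq_len(k); ir <- which(colnames(full$vcov) == "rho")
  V <- full$vcov
  eta <- full$eta
  wald_lag <- as.numeric(eta %*% solve(V[ie, ie], eta))
  g <- eta + full$rho * full$beta
  D <- cbind(diag(k) * full$rho, diag(k), full$beta)   # d g / d(beta, eta, rho)
  Vg <- D %*% V[c(ib, ie, ir), c(ib, ie, ir)] %*% t(D)
  wald_err <- as.numeric(g %*% solve(Vg, g))
  stat <- c(lr_lag, wald_lag, lr_err, wald_err)
  data.frame(test = c("lr_lag", "wald_lag", "lr_error", "wald_error"),
             statistic = stat, df = k,
             p_value = stats::pchisq(pmax(stat, 0), k, lower.tail = FALSE))
}

#' Hausman test of fixed versus random effects
#'
#' `H = (b_FE - b_RE)' [V_FE - V_RE]^(-1) (b_FE - b_RE)` on the common
#' coefficient vector; when the covariance difference is not positive
#' definite a generalized (eigenvalue-truncated) inverse is used with a
#' warning.
#'
#' @param coef_fe,coef_re coefficient vectors (same length and order).
#' @param vcov_fe,vcov_re their covariance matrices.
#' @return data.frame with `statistic`, `df`, `p_value`.
#' @export
hausman_test <- function(coef_fe, vcov_fe, coef_re, vcov_re) {
  k <- length(coef_fe)
  stopifnot(length(coef_re) == k, all(dim(vcov_fe) == k),
            all(dim(vcov_re) == k))
  d <- coef_fe - coef_re
  V <- vcov_fe - vcov_re
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values)))) {
    warning("V_FE - V_RE is not positive semidefinite; using a generalized inverse",
            call. = FALSE)
  }
  pos <- ev$values > 1e-12 * max(abs(ev$values))
  Vinv <- ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  H <- as.numeric(d %*% Vinv %*% d)
  data.frame(statistic = H, df = k,
             p_value = stats::pchisq(H, k, lower.tail = FALSE))
}

#' Classical panel Hausman test on the non-spatial model
#'
#' Runs the individual-effects within estimator against the Swamy-Arora
#' random-effects GLS estimator for `y = X beta + mu + eps` (spatial terms
#' omitted) and applies [hausman_test()] to the slope coefficients.
#'
#' @param data an [build_sdm_data()] object.
#' @return data.frame with `statistic`, `df`, `p_value`.
#' @export
panel_hausman <- function(data) {
  stopifnot(inherits(data, "sdm_data"))
  n <- data$n; tt <- data$T; N <- n * tt; k <- data$k
  y <- data$y; X <- data$X
  # within (FE)
  yt <- .demean(y, n, tt, "individual")
  Xt <- .demean(X, n, tt, "individual")
  qrX <- qr(Xt)
  b_fe <- qr.coef(qrX, yt)
  rss_w <- sum(qr.resid(qrX, yt)^2)
  s2e <- rss_w / (n * (tt - 1) - k)
  V_fe <- s2e * solve(crossprod(Xt))
  # between
  ybar <- rowMeans(matrix(y, n, tt))
  Xbar <- sapply(seq_len(k), function(j) rowMeans(matrix(X[, j], n, tt)))
  Xb1 <- cbind(1, Xbar)
  fitb <- stats::lm.fit(Xb1, ybar)
  s2b <- sum(fitb$residuals^2) / (n - k - 1)
  s2u <- max(0, s2b - s2e / tt)
  theta <- 1 - sqrt(s2e / (s2e + tt * s2u))
  # quasi-demeaned GLS (RE)
  um <- rep(ybar, tt)
  ys <- y - theta * um
  Xs <- X - theta * Xbar[rep(seq_len(n), tt), , drop = FALSE]
  Xs1 <- cbind(`(Intercept)` = 1 - theta, Xs)
  fitre <- stats::lm.fit(Xs1, ys)
  # common (within) idiosyncratic-variance estimate keeps V_FE - V_RE PSD
  V_re_full <- s2e * solve(crossprod(Xs1))
  b_re <- fitre$coefficients[-1]
  V_re <- V_re_full[-1, -1, drop = FALSE]
  hausman_test(b_fe, V_fe, b_re, V_re)
}
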