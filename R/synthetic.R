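# Synthetic provincial panels with known ground truth.
#
# The DEA generator plants units on a common supporting hyperplane of the
# two-stage technology, so true stage efficiencies are known by construction:
# inefficient units are convex combinations of frontier units with the
# initial input inflated by a factor f1 >= 1 and the final outputs deflated
# by f2 >= 1, giving true stage-1 efficiency 1/f1 (exact, single-input
# radial) and stage-2 efficiency 1/f2.  Indicator columns are then rescaled
# into the magnitude ranges typical of Chinese provincial health statistics;
# rescaling does not move CRS efficiencies.
#
# The SDM generator draws covariates i.i.d. log-normal and builds the
# dependent variable from the spatial Durbin data-generating process
# Y = (I - rho W)^(-1) (X beta + WX eta + mu + v + eps) per period.

# one master seed, deterministic named substreams
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' Configuration for the synthetic DEA panel generator
#'
#' @param n_units number of decision-making units (default 31).
#' @param years integer vector of years (default 2009:2020).
#' @param n_frontier number of efficient units per year (default 5).
#' @param ineff_stage1,ineff_stage2 ranges (length-2) of the uniform radial
#'   inefficiency factors f1, f2 for non-frontier units; default `c(1, 3)`,
#'   so true stage efficiencies 1/f span (1/3, 1].
#' @param noise_sd standard deviation of multiplicative log-normal
#'   measurement noise applied to every indicator (default 0: planted
#'   efficiencies are exact; any positive value makes them approximate and
#'   is recorded in the truth table).
#' @param weights optional `spatial_weights`; when supplied, efficient units
#'   and low inefficiency factors cluster in space (a spatially
#'   autoregressive score with coefficient `spatial_rho` orders the units),
#'   so the resulting efficiency surface is positively autocorrelated.
#' @param spatial_rho strength of the spatial clustering score (default 0.5).
#' @param seed master seed; all draws flow from it through named substreams.
#' @return list of class `synthetic_dea_config`.
#' @export
synthetic_dea_config <- function(n_units = 31, years = 2009:2020,
                                 n_frontier = 5,
                                 ineff_stage1 = c(1, 3),
                                 ineff_stage2 = c(1, 3),
                                 noise_sd = 0, weights = NULL,
                                 spatial_rho = 0.5, seed = 1) {
  stopifnot(n_frontier >= 1, n_frontier <= n_units,
            ineff_stage1[1] >= 1, ineff_stage2[1] >= 1,
            noise_sd >= 0, length(years) >= 1)
  if (!is.null(weights)) stopifnot(inherits(weights, "spatial_weights"),
                                   length(weights$units) == n_units)
  structure(list(n_units = n_units, years = as.integer(years),
                 n_frontier = n_frontier, ineff_stage1 = ineff_stage1,
                 ineff_stage2 = ineff_stage2, noise_sd = noise_sd,
                 weights = weights, spatial_rho = spatial_rho, seed = seed),
            class = "synthetic_dea_config")
}

# Table-2-like grand means for the emitted indicator columns; the three
# negative-direction indicators are emitted as reciprocals of generated
# outputs, so their generated-output targets are the reciprocal means.
.indicator_scale_targets <- c(I1 = 912, M1 = 0.753, M2 = 5.89, M3 = 4.97,
                              F1 = 23650, F2 = 83.8,
                              F3 = 0.0046, F4 = 0.0975, F5 = 1.96)

#' Generate a synthetic two-stage health-system panel with known truth
#'
#' See [synthetic_dea_config()] for the construction.  The returned panel is
#' *raw* (negative-direction indicators `F3`--`F5` are emitted as
#' reciprocals of the generated benefit outputs), so the standard pipeline
#' entry point [positivize_indicators()] restores exactly the outputs the
#' truth refers to.
#'
#' @param config a [synthetic_dea_config()].
#' @return list with `panel` (an `indicator_panel`, not positivized) and
#'   `truth` (data.frame: `unit`, `year`, `frontier`, `stage1_true`,
#'   `stage2_true`, `overall_true`, `exact` flag).
#' @export
generate_dea_panel <- function(config = synthetic_dea_config()) {
  stopifnot(inherits(config, "synthetic_dea_config"))
  n <- config$n_units
  q <- 3L; s <- 5L
  units <- if (!is.null(config$weights)) config$weights$units
           else if (n == 31) china_provinces()
           else sprintf("U%02d", seq_len(n))
  rows <- list(); truths <- list()
  for (yr in config$years) {
    set.seed(.substream(config$seed, paste0("year", yr)))
    # spatial or random ordering of units by an efficiency score
    score <- if (!is.null(config$weights)) {
      Wm <- config$weights$W
      as.vector(solve(diag(n) - config$spatial_rho * Wm, stats::rnorm(n)))
    } else stats::rnorm(n)
    ord <- order(score, decreasing = TRUE)        # best first
    frontier <- logical(n); frontier[ord[seq_len(config$n_frontier)]] <- TRUE
    # common supporting multipliers for this year's technology
    w0 <- stats::runif(q, 0.5, 1.5)
    u0 <- stats::runif(s, 0.5, 1.5)
    ray <- function() {
      gz <- stats::runif(q, 0.5, 1.5); gy <- stats::runif(s, 0.5, 1.5)
      list(z = gz / sum(w0 * gz), y = gy / sum(u0 * gy))
    }
    fr_idx <- which(frontier)
    fr <- lapply(fr_idx, function(i) ray())
    Zf <- t(vapply(fr, `[[`, numeric(q), "z"))   # w0'z = 1 rows
    Yf <- t(vapply(fr, `[[`, numeric(s), "y"))
    # inefficiency factors, coupled to the spatial score by rank
    nf <- n - config$n_frontier
    f1 <- rep(1, n); f2 <- rep(1, n)
    if (nf > 0) {
      d1 <- sort(stats::runif(nf, config$ineff_stage1[1], config$ineff_stage1[2]))
      d2 <- sort(stats::runif(nf, config$ineff_stage2[1], config$ineff_stage2[2]))
      nonf <- ord[(config$n_frontier + 1):n]     # decreasing score
      f1[nonf] <- d1                              # worse score -> larger f
      f2[nonf] <- d2
    }
    X <- numeric(n); Z <- matrix(0, n, q); Y <- matrix(0, n, s)
    for (i in seq_len(n)) {
      size <- stats::runif(1, 0.5, 2)
      if (frontier[i]) {
        j <- match(i, fr_idx)
        X[i] <- size; Z[i, ] <- size * Zf[j, ]; Y[i, ] <- size * Yf[j, ]
      } else {
        lam <- stats::rgamma(length(fr_idx), 1)
        lam <- lam / sum(lam)
        X[i] <- size * f1[i]
        Z[i, ] <- size * as.vector(lam %*% Zf)
        Y[i, ] <- size * as.vector(lam %*% Yf) / f2[i]
      }
    }
    if (config$noise_sd > 0) {
      X <- X * exp(stats::rnorm(n, 0, config$noise_sd))
      Z <- Z * exp(matrix(stats::rnorm(n * q, 0, config$noise_sd), n))
      Y <- Y * exp(matrix(stats::rnorm(n * s, 0, config$noise_sd), n))
    }
    rows[[as.character(yr)]] <- data.frame(
      unit = units, year = yr, I1 = X,
      M1 = Z[, 1], M2 = Z[, 2], M3 = Z[, 3],
      F1 = Y[, 1], F2 = Y[, 2], F3 = Y[, 3], F4 = Y[, 4], F5 = Y[, 5],
      stringsAsFactors = FALSE)
    truths[[as.character(yr)]] <- data.frame(
      unit = units, year = yr, frontier = frontier,
      stage1_true = 1 / f1, stage2_true = 1 / f2,
      overall_true = 1 / (f1 * f2), exact = config$noise_sd == 0,
      stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  # rescale columns into realistic indicator magnitudes
  tg <- .indicator_scale_targets
  for (cl in c("I1", "M1", "M2", "M3", "F1", "F2")) {
    panel[[cl]] <- panel[[cl]] * tg[[cl]] / mean(panel[[cl]])
  }
  for (cl in c("F3", "F4", "F5")) {   # scale benefit output, then emit reciprocal
    v <- panel[[cl]] * (1 / tg[[cl]]) / mean(panel[[cl]])
    panel[[cl]] <- 1 / v
  }
  rownames(panel) <- NULL
  list(panel = as_indicator_panel(panel, positivized = FALSE),
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
}

#' Configuration for the synthetic spatial Durbin panel generator
#'
#' Defaults emulate the scale of the provincial efficiency regression:
#' 5 covariates whose logs enter the model, coefficient magnitudes matching
#' the fitted provincial model, error standard deviation 0.1 (error
#' variance about 0.01), and moderate unit/time effects.
#'
#' @param n_units,T panel dimensions (defaults 31 and 12).
#' @param rho spatial autoregressive coefficient (|rho| < 1).
#' @param beta,eta covariate and spatial-lag coefficient vectors (length 5
#'   by default: lnpgdp, lnfiscal, lnurban, lnedu, lndepend).
#' @param sigma error standard deviation.
#' @param unit_sd,time_sd standard deviations of the drawn unit and time
#'   effects.
#' @param cov_meanlog,cov_sdlog log-normal parameters of the raw
#'   covariates, one per covariate.
#' @param cov_unit_sdlog standard deviation of a persistent unit-level
#'   component added to the log covariates (default 0: covariates i.i.d.
#'   across unit-years; positive values emulate the persistent cross-unit
#'   heterogeneity of real provincial covariates).
#' @param seed master seed.
#' @return list of class `synthetic_sdm_config`.
#' @export
synthetic_sdm_config <- function(n_units = 31, T = 12, rho = 0.4,
                                 beta = c(-0.66, -0.30, -0.18, -0.04, 0.26),
                                 eta = c(1.20, -0.53, -0.31, -0.11, 0.37),
                                 sigma = 0.1, unit_sd = 0.1, time_sd = 0.05,
                                 cov_meanlog = log(c(45846, 7.04, 0.55,
                                                     6.10, 13.97)),
                                 cov_sdlog = c(0.5, 0.4, 0.15, 0.6, 0.25),
                                 cov_unit_sdlog = 0, seed = 1) {
  stopifnot(abs(rho) < 1, length(beta) == length(eta),
            length(cov_meanlog) == length(beta),
            length(cov_sdlog) == length(beta), sigma >= 0, T >= 2)
  structure(list(n_units = n_units, T = as.integer(T), rho = rho,
                 beta = beta, eta = eta, sigma = sigma, unit_sd = unit_sd,
                 time_sd = time_sd, cov_meanlog = cov_meanlog,
                 cov_sdlog = cov_sdlog, cov_unit_sdlog = cov_unit_sdlog,
                 seed = seed),
            class = "synthetic_sdm_config")
}

#' Generate covariates and dependent variable from the SDM process
#'
#' @param config a [synthetic_sdm_config()].
#' @param weights row-standardized `spatial_weights` with
#'   `config$n_units` units.
#' @param years year labels (default `2009 + 0:(T-1)`).
#' @return list with `covariates` (a `covariate_panel`), `y` (data.frame
#'   `unit`, `year`, `overall`), and `truth` (the DGP parameters and drawn
#'   effects).
#' @export
generate_sdm_panel <- function(config = synthetic_sdm_config(),
                               weights,
                               years = NULL) {
  stopifnot(inherits(config, "synthetic_sdm_config"),
            inherits(weights, "spatial_weights"))
  if (!weights$standardized) weights <- row_standardize(weights)
  n <- config$n_units
  stopifnot(length(weights$units) == n)
  tt <- config$T
  if (is.null(years)) years <- 2009 + seq_len(tt) - 1
  stopifnot(length(years) == tt)
  units <- weights$units
  W <- weights$W
  k <- length(config$beta)
  set.seed(.substream(config$seed, "covariates"))
  Xl <- matrix(stats::rnorm(n * tt * k), n * tt, k)
  Xl <- sweep(Xl, 2, config$cov_sdlog, "*")
  Xl <- sweep(Xl, 2, config$cov_meanlog, "+")      # log covariates
  if (config$cov_unit_sdlog > 0) {
    set.seed(.substream(config$seed, "cov_unit"))
    a <- matrix(stats::rnorm(n * k, 0, config$cov_unit_sdlog), n, k)
    Xl <- Xl + a[rep(seq_len(n), tt), , drop = FALSE]
  }
  set.seed(.substream(config$seed, "effects"))
  mu <- stats::rnorm(n, 0, config$unit_sd)
  v <- stats::rnorm(tt, 0, config$time_sd)
  set.seed(.substream(config$seed, "errors"))
  eps <- stats::rnorm(n * tt, 0, config$sigma)
  B <- diag(n) - config$rho * W
  y <- numeric(n * tt)
  for (t in seq_len(tt)) {
    i <- (t - 1) * n + seq_len(n)
    xb <- Xl[i, , drop = FALSE] %*% config$beta +
      (W %*% Xl[i, , drop = FALSE]) %*% config$eta
    rhs <- as.vector(xb) + mu + v[t] + eps[i]
    y[i] <- if (config$rho == 0) rhs else as.vector(solve(B, rhs))
  }
  cov_df <- data.frame(unit = rep(units, tt),
                       year = rep(years, each = n),
                       exp(Xl), stringsAsFactors = FALSE)
  names(cov_df)[-(1:2)] <- covariate_cols()
  ydf <- data.frame(unit = rep(units, tt), year = rep(years, each = n),
                    overall = y, stringsAsFactors = FALSE)
  list(covariates = as_covariate_panel(cov_df), y = ydf,
       truth = list(rho = config$rho, beta = config$beta, eta = config$eta,
                    sigma = config$sigma, mu = mu, v = v))
}
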