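# Shared fixtures and independent oracles, all built in code.

# rook-contiguity pair list for an nr x nc grid of labelled cells
grid_pairs <- function(nr, nc) {
  id <- function(r, c) sprintf("g%02d_%02d", r, c)
  from <- character(0); to <- character(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1)) }
    if (r < nr) { from <- c(from, id(r, c)); to <- c(to, id(r + 1, c)) }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

grid_units <- function(nr, nc) {
  sort(unique(unlist(grid_pairs(nr, nc)[, 1:2])))
}

grid_weights <- function(nr, nc, standardize = TRUE) {
  build_weights(grid_pairs(nr, nc), grid_units(nr, nc),
                standardize = standardize)
}

# a tiny valid raw indicator panel (2 units x 2 years) for IO tests
tiny_indicator_df <- function() {
  expand <- expand.grid(unit = c("A", "B"), year = c(2009L, 2010L),
                        stringsAsFactors = FALSE)
  cbind(expand,
        I1 = c(900, 1100, 950, 1050), M1 = c(0.7, 0.8, 0.72, 0.81),
        M2 = c(5.5, 6.0, 5.6, 6.1), M3 = c(4.8, 5.1, 4.9, 5.2),
        F1 = c(20000, 26000, 21000, 25000), F2 = c(80, 86, 81, 85),
        F3 = c(0.004, 0.005, 0.0041, 0.0049),
        F4 = c(0.09, 0.5, 0.11, 0.1), F5 = c(1.8, 2.1, 1.9, 2.0))
}

# ---- brute-force ratio-form CCR oracle (dims <= 2) --------------------------
# Maximizes (u'Y_k / v'X_k) / max_j (u'Y_j / v'X_j) over normalized
# multiplier directions: coarse grid then Nelder-Mead polish.  Independent
# of the LP path.
ccr_oracle <- function(X, Y, k, grid_n = 60) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  a <- ncol(X); b <- ncol(Y)
  stopifnot(a <= 2, b <= 2)
  ratio_score <- function(u, v) {
    num <- as.vector(Y %*% u)
    den <- as.vector(X %*% v)
    r <- num / den
    r[k] / max(r)
  }
  ts <- seq(0.002, 0.998, length.out = grid_n)
  us <- if (b == 2) lapply(ts, function(t) c(t, 1 - t)) else list(1)
  vs <- if (a == 2) lapply(ts, function(t) c(t, 1 - t)) else list(1)
  best <- -Inf; best_uv <- NULL
  for (u in us) for (v in vs) {
    s <- ratio_score(u, v)
    if (s > best) { best <- s; best_uv <- c(u, v) }
  }
  # polish on unconstrained log scale
  f <- function(th) {
    u <- exp(th[seq_len(b)]); v <- exp(th[b + seq_len(a)])
    -ratio_score(u, v)
  }
  op <- stats::optim(log(pmax(best_uv, 1e-8)), f, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  max(best, -op$value)
}

# ---- multistart nonlinear oracle for the relational model (m = 1) -----------
# For a single initial input the input multiplier cancels; for any positive
# (u, w) the best jointly feasible scaling gives score
#   min(1/A, 1/(B C)) * u'Y_k / x_k
# with A = max_j u'Y_j / x_j, B = max_j w'Z_j / x_j, C = max_j u'Y_j / w'Z_j.
# Maximized over (u, w) by Nelder-Mead from random starts.
relational_oracle <- function(inst, k, n_starts = 100, seed = 1) {
  stopifnot(ncol(inst$X) == 1)
  x <- as.vector(inst$X); Z <- inst$Z; Y <- inst$Y
  q <- ncol(Z); s <- ncol(Y)
  score <- function(u, w) {
    yu <- as.vector(Y %*% u); zw <- as.vector(Z %*% w)
    A <- max(yu / x); B <- max(zw / x); C <- max(yu / zw)
    min(1 / A, 1 / (B * C)) * yu[k] / x[k]
  }
  f <- function(th) -score(exp(th[seq_len(s)]), exp(th[s + seq_len(q)]))
  set.seed(seed)
  best <- -Inf
  for (i in seq_len(n_starts)) {
    th0 <- stats::rnorm(s + q)
    op <- stats::optim(th0, f, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-12))
    best <- max(best, -op$value)
  }
  best
}

# ---- exhaustive contiguous-partition oracle for natural breaks --------------
# Enumerates all ways to split the sorted values into k contiguous classes
# and returns the minimal within-class sum of squared deviations.
jenks_oracle <- function(values, k) {
  xs <- sort(values)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (cc in seq_len(k)) tot <- tot + ssd(xs[(b[cc] + 1):b[cc + 1]])
    best <- min(best, tot)
  }
  best
}

# random small two-stage instance
random_instance <- function(n, m, q, s) {
  dea_instance(X = matrix(stats::runif(n * m, 0.5, 2), n),
               Z = matrix(stats::runif(n * q, 0.5, 2), n),
               Y = matrix(stats::runif(n * s, 0.5, 2), n))
}
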