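# Relational two-stage network DEA under constant returns to scale.
#
# Stage 1 (resource allocation) turns the initial input X into intermediate
# outputs Z; stage 2 (service operation) turns Z into final outputs Y.  The
# relational model scores both stages with one shared multiplier set, so the
# overall efficiency factorizes exactly as E = E1 * E2.  All models are the
# multiplier ("ratio") form linearized by fixing the evaluated unit's
# weighted input at 1, and solved as dense LPs.
#
# Columns of X, Z, Y are normalized to unit mean internally before solving;
# CRS efficiency is invariant to per-column rescaling, and applying the
# non-Archimedean bound epsilon in the normalized space makes results both
# well conditioned and exactly units-invariant.

#' DEA solver configuration
#'
#' @param epsilon non-Archimedean lower bound on all multipliers, applied to
#'   column-normalized data (each column of X, Z, Y scaled to mean 1).
#'   Must be positive and small; default `1e-6`.
#' @param lp_tolerance pivot/feasibility tolerance of the LP backend.
#' @param priority which stage is maximized first when decomposing overall
#'   efficiency (`"stage1_first"`, the default, or `"stage2_first"`).  The
#'   optimal multipliers need not be unique, so the two orders can disagree;
#'   both are computed by [run_dea_year()] and disagreements are flagged.
#' @return list of class `dea_config`.
#' @export
dea_config <- function(epsilon = 1e-6, lp_tolerance = 1e-9,
                       priority = c("stage1_first", "stage2_first")) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0,
            epsilon < 1e-2, lp_tolerance > 0)
  structure(list(epsilon = epsilon, lp_tolerance = lp_tolerance,
                 priority = match.arg(priority)),
            class = "dea_config")
}

#' Assemble a two-stage DEA instance
#'
#' @param X n x m matrix of initial inputs (strictly positive).
#' @param Z n x q matrix of intermediate outputs.
#' @param Y n x s matrix of final outputs.
#' @param units optional unit labels (default rownames of `X` or indices).
#' @return list of class `dea_instance` with elements `X`, `Z`, `Y`, `units`.
#' @export
dea_instance <- function(X, Z, Y, units = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n >= 1, nrow(Z) == n, nrow(Y) == n,
            ncol(X) >= 1, ncol(Z) >= 1, ncol(Y) >= 1)
  for (nm in c("X", "Z", "Y")) {
    M <- get(nm)
    if (!all(is.finite(M)) || any(M <= 0)) {
      stop(sprintf("all entries of %s must be strictly positive and finite", nm),
           call. = FALSE)
    }
  }
  if (is.null(units)) units <- rownames(X)
  if (is.null(units)) units <- as.character(seq_len(n))
  stopifnot(length(units) == n)
  structure(list(X = X, Z = Z, Y = Y, units = units), class = "dea_instance")
}

# column-normalize a matrix to unit mean (positive entries guaranteed)
.colnorm <- function(M) sweep(M, 2, colMeans(M), "/")

# Solve max obj'theta subject to A theta (dir) rhs and theta >= eps,
# via the shift theta = eps + t.
.dea_lp <- function(obj, A, dir, rhs, eps, tol) {
  lb <- rep(eps, length(obj))
  res <- lp_solve(obj, A, dir, rhs - as.vector(A %*% lb), maximize = TRUE,
                  tol = tol)
  if (res$status == "optimal") {
    res$objective <- res$objective + sum(obj * lb)
    res$x <- res$x + lb
  }
  res
}

#' Single-technology CCR efficiency (multiplier form)
#'
#' Scores unit `k` for the technology `inputs -> outputs` under constant
#' returns to scale: the maximum of weighted output over weighted input,
#' subject to every unit's ratio being at most 1 and all multipliers at
#' least epsilon.  Used with (X, Y) for the independent overall model,
#' (X, Z) for stage 1 alone, and (Z, Y) for stage 2 alone.
#'
#' @param inputs n x a positive matrix.
#' @param outputs n x b positive matrix.
#' @param k index of the evaluated unit.
#' @param config a [dea_config()].
#' @return list with `score` in (0, 1], multipliers `u` (outputs) and `v`
#'   (inputs) on the column-normalized scale, and `status`.
#' @export
ccr_efficiency <- function(inputs, outputs, k, config = dea_config()) {
  Xn <- .colnorm(as.matrix(inputs)); Yn <- .colnorm(as.matrix(outputs))
  n <- nrow(Xn); a <- ncol(Xn); b <- ncol(Yn)
  stopifnot(k >= 1, k <= n)
  # variables: (u_1..u_b, v_1..v_a)
  obj <- c(Yn[k, ], rep(0, a))
  A <- rbind(c(rep(0, b), Xn[k, ]),        # v'X_k = 1
             cbind(Yn, -Xn))               # u'Y_j - v'X_j <= 0
  dir <- c("==", rep("<=", n))
  rhs <- c(1, rep(0, n))
  res <- .dea_lp(obj, A, dir, rhs, config$epsilon, config$lp_tolerance)
  if (res$status != "optimal") {
    stop(sprintf(
      "CCR LP for unit %d did not solve (status '%s'); epsilon = %g may be too large for this instance",
      k, res$status, config$epsilon), call. = FALSE)
  }
  list(score = res$objective, u = res$x[seq_len(b)],
       v = res$x[b + seq_len(a)], status = res$status)
}

# build the shared constraint block of the relational model on normalized
# matrices: variables (u, v, w); rows: u'Y_j - v'X_j <= 0 ; w'Z_j - v'X_j <= 0 ;
# u'Y_j - w'Z_j <= 0
.relational_constraints <- function(Xn, Zn, Yn) {
  n <- nrow(Xn); m <- ncol(Xn); q <- ncol(Zn); s <- ncol(Yn)
  zero_q <- matrix(0, n, q); zero_s <- matrix(0, n, s); zero_m <- matrix(0, n, m)
  A <- rbind(cbind(Yn, -Xn, zero_q),
             cbind(zero_s, -Xn, Zn),
             cbind(Yn, zero_m, -Zn))
  list(A = A, dir = rep("<=", 3L * n), rhs = rep(0, 3L * n),
       m = m, q = q, s = s)
}

#' Relational overall efficiency of a two-stage system
#'
#' Maximizes unit `k`'s weighted final output with its weighted initial
#' input fixed at 1, under three families of constraints -- overall, stage-1
#' and stage-2 ratios of every unit at most 1 -- with one multiplier set
#' shared by both stages.  The optimum therefore satisfies
#' `E_overall = E_stage1 * E_stage2` (see [decompose_stages()]).
#'
#' @param instance a [dea_instance()].
#' @inheritParams ccr_efficiency
#' @return list with `score`, multipliers `u`, `v`, `w` (normalized scale),
#'   and `status`.
#' @export
relational_overall <- function(instance, k, config = dea_config()) {
  stopifnot(inherits(instance, "dea_instance"))
  Xn <- .colnorm(instance$X); Zn <- .colnorm(instance$Z)
  Yn <- .colnorm(instance$Y)
  n <- nrow(Xn)
  stopifnot(k >= 1, k <= n)
  cb <- .relational_constraints(Xn, Zn, Yn)
  m <- cb$m; q <- cb$q; s <- cb$s
  obj <- c(Yn[k, ], rep(0, m + q))
  A <- rbind(c(rep(0, s), Xn[k, ], rep(0, q)), cb$A)
  dir <- c("==", cb$dir)
  rhs <- c(1, cb$rhs)
  res <- .dea_lp(obj, A, dir, rhs, config$epsilon, config$lp_tolerance)
  if (res$status != "optimal") {
    stop(sprintf(
      "relational LP for unit %d did not solve (status '%s'); epsilon = %g may be too large",
      k, res$status, config$epsilon), call. = FALSE)
  }
  list(score = res$objective, u = res$x[seq_len(s)],
       v = res$x[s + seq_len(m)], w = res$x[s + m + seq_len(q)],
       status = res$status)
}

#' Decompose overall efficiency into stage efficiencies
#'
#' With `priority = "stage1_first"` the stage-1 (resource allocation)
#' efficiency is maximized subject to the overall efficiency being held at
#' `e_overall`, and stage 2 follows as `E2 = E / E1`; with
#' `"stage2_first"` the roles are swapped.  The overall score is pinned by
#' an equality constraint with a `1e-9` slack so floating-point noise from
#' the first solve cannot make the second infeasible.
#'
#' @param instance a [dea_instance()].
#' @param k evaluated unit index.
#' @param e_overall overall efficiency previously computed by
#'   [relational_overall()] for the same instance and config.
#' @param config a [dea_config()]; `config$priority` selects the order.
#' @return list with `stage1`, `stage2` (both in (0, 1], product equal to
#'   `e_overall` within `1e-6`), multipliers and `status`.
#' @export
decompose_stages <- function(instance, k, e_overall, config = dea_config()) {
  stopifnot(inherits(instance, "dea_instance"),
            is.numeric(e_overall), length(e_overall) == 1,
            e_overall > 0, e_overall <= 1 + 1e-9)
  Xn <- .colnorm(instance$X); Zn <- .colnorm(instance$Z)
  Yn <- .colnorm(instance$Y)
  n <- nrow(Xn)
  stopifnot(k >= 1, k <= n)
  cb <- .relational_constraints(Xn, Zn, Yn)
  m <- cb$m; q <- cb$q; s <- cb$s
  slack <- 1e-9
  # overall efficiency pinned: u'Y_k - E v'X_k in [-slack, +slack]
  pin <- c(Yn[k, ], -e_overall * Xn[k, ], rep(0, q))
  if (config$priority == "stage1_first") {
    obj <- c(rep(0, s + m), Zn[k, ])                 # max w'Z_k
    norm_row <- c(rep(0, s), Xn[k, ], rep(0, q))     # v'X_k = 1
  } else {
    obj <- c(Yn[k, ], rep(0, m + q))                 # max u'Y_k
    norm_row <- c(rep(0, s + m), Zn[k, ])            # w'Z_k = 1
  }
  A <- rbind(norm_row, pin, pin, cb$A)
  dir <- c("==", "<=", ">=", cb$dir)
  rhs <- c(1, slack, -slack, cb$rhs)
  res <- .dea_lp(obj, A, dir, rhs, config$epsilon, config$lp_tolerance)
  if (res$status != "optimal") {
    stop(sprintf(
      "stage decomposition LP for unit %d infeasible at fixed overall efficiency %.12f (status '%s'); solver tolerances of the two solves disagree",
      k, e_overall, res$status), call. = FALSE)
  }
  if (config$priority == "stage1_first") {
    stage1 <- res$objective
    stage2 <- e_overall / stage1
  } else {
    stage2 <- res$objective
    stage1 <- e_overall / stage2
  }
  list(stage1 = stage1, stage2 = stage2,
       u = res$x[seq_len(s)], v = res$x[s + seq_len(m)],
       w = res$x[s + m + seq_len(q)], status = res$status)
}

#' Score one year's cross-section of the health-system panel
#'
#' Builds the year's two-stage instance from a positivized indicator panel
#' -- X = (I1), Z = (M1, M2, M3), Y = (F1, F2, 1/F3, 1/F4, 1/F5) -- and
#' returns overall, resource-allocation (stage 1) and service-operation
#' (stage 2) efficiencies for every unit.  The frontier is cross-sectional:
#' each year is scored against that year's units only.
#'
#' Both decomposition orders are computed; when they disagree by more than
#' `1e-6` the optimal multiplier set is not unique and the unit is flagged
#' in the `nonunique` column (the reported stages follow `config$priority`).
#'
#' @param panel an `indicator_panel` with `positivized = TRUE`.
#' @param year the year to score (must be present in the panel).
#' @param config a [dea_config()].
#' @return data.frame of class `dea_scores` with columns `unit`, `year`,
#'   `overall`, `stage1`, `stage2`, `status`, `nonunique`.
#' @export
run_dea_year <- function(panel, year, config = dea_config()) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (!isTRUE(attr(panel, "positivized"))) {
    stop("panel must be positivized before DEA (see positivize_indicators())",
         call. = FALSE)
  }
  sub <- panel[panel$year == year, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("year %s not present in panel", year),
                       call. = FALSE)
  inst <- dea_instance(X = as.matrix(sub[, "I1", drop = FALSE]),
                       Z = as.matrix(sub[, c("M1", "M2", "M3")]),
                       Y = as.matrix(sub[, c("F1", "F2", "F3", "F4", "F5")]),
                       units = sub$unit)
  n <- nrow(inst$X)
  alt <- config
  alt$priority <- setdiff(c("stage1_first", "stage2_first"), config$priority)
  out <- data.frame(unit = inst$units, year = year, overall = NA_real_,
                    stage1 = NA_real_, stage2 = NA_real_,
                    status = NA_character_, nonunique = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    ov <- tryCatch(relational_overall(inst, k, config), error = function(e) e)
    if (inherits(ov, "error")) {
      stop(sprintf("unit '%s', year %s: %s", inst$units[k], year,
                   conditionMessage(ov)), call. = FALSE)
    }
    dec <- decompose_stages(inst, k, ov$score, config)
    dec_alt <- decompose_stages(inst, k, ov$score, alt)
    out$overall[k] <- min(ov$score, 1)
    out$stage1[k] <- min(dec$stage1, 1)
    out$stage2[k] <- min(dec$stage2, 1)
    out$status[k] <- dec$status
    out$nonunique[k] <- abs(dec$stage1 - dec_alt$stage1) > 1e-6
    if (abs(ov$score - dec$stage1 * dec$stage2) > 1e-6) {
      stop(sprintf(
        "unit '%s', year %s: product identity violated (|E - E1*E2| = %g)",
        inst$units[k], year, abs(ov$score - dec$stage1 * dec$stage2)),
        call. = FALSE)
    }
  }
  dims <- ncol(inst$X) + ncol(inst$Z) + ncol(inst$Y)
  near <- 10 * config$epsilon * dims
  sc <- c(out$overall, out$stage1, out$stage2)
  # scores numerically at 1 (within LP tolerance) are frontier, not sensitive
  at_bound <- sc > 1 - 100 * config$lp_tolerance
  if (any(sc < near | (!at_bound & sc > 1 - near))) {
    warning(sprintf(
      "some efficiency scores lie within %.2g of a bound; results may be sensitive to epsilon = %g",
      near, config$epsilon), call. = FALSE)
  }
  structure(out, class = c("dea_scores", "data.frame"),
            epsilon = config$epsilon, priority = config$priority)
}

#' Score every year of a positivized indicator panel
#'
#' Convenience wrapper that applies [run_dea_year()] to each year and binds
#' the per-year score tables.
#'
#' @inheritParams run_dea_year
#' @return `dea_scores` data.frame covering all unit-years.
#' @export
run_dea_panel <- function(panel, config = dea_config()) {
  years <- sort(unique(panel$year))
  res <- do.call(rbind, lapply(years, function(y)
    as.data.frame(run_dea_year(panel, y, config))))
  structure(res, class = c("dea_scores", "data.frame"),
            epsilon = config$epsilon, priority = config$priority)
}
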