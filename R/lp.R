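# Dense two-phase simplex for the small multiplier-form linear programs that
# the network DEA models generate (tens of constraints, ~10 variables).
# Tableau method with Dantzig pricing, falling back to Bland's rule to break
# degenerate cycling -- DEA multiplier LPs are routinely degenerate.

#' Solve a small dense linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x (dir) rhs` and
#' `x >= 0`, where `dir` is a vector of `"<="`, `">="`, `"=="` per row.
#' Intended for the multiplier-form DEA programs built by this package; the
#' interface is a generic LP contract so the backend can be swapped.
#'
#' @param obj numeric objective coefficient vector.
#' @param A constraint coefficient matrix (rows = constraints).
#' @param dir character vector of constraint directions, one of
#'   `"<="`, `">="`, `"=="` per row.
#' @param rhs numeric right-hand-side vector.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance. Default `1e-9`.
#' @param max_iter iteration cap; defaults to `200 * (nrow(A) + ncol(A))`.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `objective`, and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, maximize = TRUE, tol = 1e-9,
                     max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  nv <- ncol(A)
  stopifnot(length(obj) == nv, length(dir) == m, length(rhs) == m)
  if (!all(dir %in% c("<=", ">=", "=="))) {
    stop("constraint directions must be one of '<=', '>=', '=='")
  }
  if (is.null(max_iter)) max_iter <- 200L * (m + nv)
  cvec <- if (maximize) obj else -obj

  # normalize to rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  need_art <- dir %in% c(">=", "==")
  n_art <- sum(need_art)

  ncols <- nv + n_le + n_ge + n_art
  M <- matrix(0, m, ncols)
  M[, seq_len(nv)] <- A
  basis <- integer(m)
  slack_at <- nv
  art_at <- nv + n_le + n_ge
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_at <- slack_at + 1L
      M[i, slack_at] <- 1
      basis[i] <- slack_at
    } else if (dir[i] == ">=") {
      slack_at <- slack_at + 1L
      M[i, slack_at] <- -1
    }
    if (need_art[i]) {
      art_at <- art_at + 1L
      M[i, art_at] <- 1
      basis[i] <- art_at
    }
  }
  art_cols <- seq(nv + n_le + n_ge + 1L, length.out = n_art)

  Tab <- rbind(cbind(M, rhs), 0)
  obj_row <- m + 1L
  rhs_col <- ncols + 1L

  canonicalize <- function(Tab, basis, costs) {
    Tab[obj_row, ] <- c(-costs, 0)
    for (i in seq_len(m)) {
      piv <- Tab[i, basis[i]]
      if (abs(piv - 1) > tol) Tab[i, ] <- Tab[i, ] / piv
      cf <- Tab[obj_row, basis[i]]
      if (abs(cf) > 0) Tab[obj_row, ] <- Tab[obj_row, ] - cf * Tab[i, ]
    }
    Tab
  }

  run_phase <- function(Tab, basis, allowed) {
    it <- 0L
    bland_after <- max_iter %/% 2L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(Tab = Tab, basis = basis, code = "maxiter"))
      red <- Tab[obj_row, seq_len(ncols)]
      red[!allowed] <- Inf   # never enter disallowed columns
      cand <- which(red < -tol)
      if (!length(cand)) return(list(Tab = Tab, basis = basis, code = "optimal"))
      enter <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
      col <- Tab[seq_len(m), enter]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tab = Tab, basis = basis, code = "unbounded"))
      ratio <- Tab[pos, rhs_col] / col[pos]
      leave_candidates <- pos[ratio <= min(ratio) + tol]
      # Bland-style tie break: smallest basis index among ties
      leave <- leave_candidates[which.min(basis[leave_candidates])]
      piv <- Tab[leave, enter]
      Tab[leave, ] <- Tab[leave, ] / piv
      other <- setdiff(seq_len(obj_row), leave)
      Tab[other, ] <- Tab[other, ] - outer(Tab[other, enter], Tab[leave, ])
      basis[leave] <- enter
    }
  }

  allowed_all <- rep(TRUE, ncols)

  # Phase 1: drive artificials to zero
  if (n_art > 0) {
    costs1 <- rep(0, ncols)
    costs1[art_cols] <- -1
    Tab <- canonicalize(Tab, basis, costs1)
    ph1 <- run_phase(Tab, basis, allowed_all)
    Tab <- ph1$Tab
    basis <- ph1$basis
    if (ph1$code == "maxiter") {
      return(list(status = "maxiter", objective = NA_real_, x = rep(NA_real_, nv)))
    }
    scale1 <- max(1, abs(rhs))
    if (Tab[obj_row, rhs_col] < -tol * scale1 * 100) {
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, nv)))
    }
    # pivot remaining basic artificials out where possible
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        row <- Tab[i, seq_len(nv + n_le + n_ge)]
        j <- which(abs(row) > tol)[1L]
        if (!is.na(j)) {
          piv <- Tab[i, j]
          Tab[i, ] <- Tab[i, ] / piv
          other <- setdiff(seq_len(obj_row), i)
          Tab[other, ] <- Tab[other, ] - outer(Tab[other, j], Tab[i, ])
          basis[i] <- j
        }
      }
    }
  }

  # Phase 2
  costs2 <- c(cvec, rep(0, ncols - nv))
  costs2[art_cols] <- 0
  allowed2 <- allowed_all
  allowed2[art_cols] <- FALSE
  Tab <- canonicalize(Tab, basis, costs2)
  ph2 <- run_phase(Tab, basis, allowed2)
  Tab <- ph2$Tab
  basis <- ph2$basis
  if (ph2$code != "optimal") {
    return(list(status = ph2$code, objective = NA_real_, x = rep(NA_real_, nv)))
  }

  x <- numeric(ncols)
  x[basis] <- Tab[seq_len(m), rhs_col]
  xs <- x[seq_len(nv)]
  val <- sum(cvec * xs)
  list(status = "optimal",
       objective = if (maximize) val else -val,
       x = xs)
}
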