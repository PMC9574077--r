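# Contiguity weight matrices and global Moran's I with normal-approximation
# and permutation inference.

#' Build a contiguity spatial weight matrix
#'
#' Turns a pair list of contiguous units into a binary symmetric n x n
#' matrix with zero diagonal, optionally row-standardized (each nonzero row
#' divided by its sum -- the convention for the autocorrelation and spatial
#' regression models in this package).
#'
#' @param pairs data.frame or 2-column matrix of contiguity pairs (unordered;
#'   each pair may appear once, symmetry is enforced).
#' @param units character vector of all unit labels, fixing row/column order.
#' @param standardize row-standardize the matrix (default `TRUE`).
#' @param islands what to do with units that have no neighbour: `"error"`
#'   (default -- an unlinked island makes row standardization undefined) or
#'   `"allow"` (keep an all-zero row).
#' @return object of class `spatial_weights`: list with `W` (n x n matrix),
#'   `units`, and `standardized` flag.
#' @export
build_weights <- function(pairs, units, standardize = TRUE,
                          islands = c("error", "allow")) {
  islands <- match.arg(islands)
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  unknown <- setdiff(c(a, b), units)
  if (length(unknown)) {
    stop(sprintf("pair list references unknown unit(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  n <- length(units)
  W <- matrix(0, n, n, dimnames = list(units, units))
  ia <- match(a, units); ib <- match(b, units)
  if (any(ia == ib)) stop("self-pair in contiguity list", call. = FALSE)
  W[cbind(ia, ib)] <- 1
  W[cbind(ib, ia)] <- 1
  iso <- units[rowSums(W) == 0]
  if (length(iso) && islands == "error") {
    stop(sprintf(
      "isolated unit(s) with no neighbour: %s (supply an island link or islands = 'allow')",
      paste(iso, collapse = ", ")), call. = FALSE)
  }
  w <- structure(list(W = W, units = units, standardized = FALSE),
                 class = "spatial_weights")
  if (standardize) w <- row_standardize(w) else w
}

#' Row-standardize a spatial weight matrix
#'
#' Divides every row with at least one neighbour by its sum; idempotent.
#'
#' @param w a `spatial_weights` object.
#' @return the standardized `spatial_weights`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- rowSums(w$W)
  pos <- rs > 0
  w$W[pos, ] <- w$W[pos, , drop = FALSE] / rs[pos]
  w$standardized <- TRUE
  w
}

.weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Global Moran's I statistic
#'
#' The classic cross-product statistic
#' `I = sum_ij W_ij (x_i - xbar)(x_j - xbar) / (S2 * sum_ij W_ij)` with
#' `S2 = sum_i (x_i - xbar)^2 / n`; defined for any nonnegative weight
#' matrix with zero diagonal, standardized or not.  Invariant to affine
#' transformations of `x`.
#'
#' @param x numeric vector, one value per unit (aligned with the weights).
#' @param W a `spatial_weights` object or a plain nonnegative matrix.
#' @return the Moran's I statistic (scalar).
#' @export
morans_i <- function(x, W) {
  M <- .weights_matrix(W)
  n <- length(x)
  stopifnot(nrow(M) == n, ncol(M) == n)
  if (anyNA(x)) stop("missing values in x", call. = FALSE)
  z <- x - mean(x)
  s2 <- sum(z^2) / n
  if (s2 <= 0) stop("Moran's I undefined: x is constant (zero variance)",
                    call. = FALSE)
  s0 <- sum(M)
  if (s0 <= 0) stop("weight matrix has no nonzero entries", call. = FALSE)
  sum(M * tcrossprod(z)) / (s2 * s0)
}

#' Moran's I with inference
#'
#' Under spatial randomness `E[I] = -1/(n-1)`.  The `"normal"` method uses
#' the closed-form randomization (permutation-moment) variance of I and a
#' one-sided (or two-sided) normal approximation; the `"permutation"`
#' method compares the observed I with its distribution over random
#' relabelings of `x` (one-sided p, rank-based, never exactly zero).
#'
#' @inheritParams morans_i
#' @param method `"permutation"` (default, 999 shuffles) or `"normal"`.
#' @param n_permutations number of shuffles for the permutation method
#'   (at least 99).
#' @param seed integer seed fixing the shuffle stream (optional).
#' @param alternative `"greater"` (positive autocorrelation, default) or
#'   `"two.sided"`.
#' @return object of class `moran_test`: list with `I`, `expected`, `sd`,
#'   `z`, `p_value`, `method`, `n_permutations`, `seed`, `alternative`.
#' @export
moran_inference <- function(x, W, method = c("permutation", "normal"),
                            n_permutations = 999, seed = NULL,
                            alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  M <- .weights_matrix(W)
  n <- length(x)
  I_obs <- morans_i(x, M)
  e_i <- -1 / (n - 1)
  if (method == "normal") {
    z0 <- x - mean(x)
    s0 <- sum(M)
    s1 <- 0.5 * sum((M + t(M))^2)
    s2 <- sum((rowSums(M) + colSums(M))^2)
    b2 <- n * sum(z0^4) / (sum(z0^2)^2)
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
             ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
    sd_i <- sqrt(var_i)
    zval <- (I_obs - e_i) / sd_i
    p <- if (alternative == "greater") stats::pnorm(zval, lower.tail = FALSE)
         else 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
    perms <- NA_integer_
  } else {
    if (n_permutations < 99) stop("need at least 99 permutations",
                                  call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    I_perm <- replicate(n_permutations, morans_i(sample(x), M))
    sd_i <- stats::sd(I_perm)
    zval <- (I_obs - mean(I_perm)) / sd_i
    p <- if (alternative == "greater") {
      (1 + sum(I_perm >= I_obs)) / (n_permutations + 1)
    } else {
      (1 + sum(abs(I_perm - mean(I_perm)) >= abs(I_obs - mean(I_perm)))) /
        (n_permutations + 1)
    }
    perms <- n_permutations
  }
  structure(list(I = I_obs, expected = e_i, sd = sd_i, z = zval, p_value = p,
                 method = method, n_permutations = perms,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 alternative = alternative),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), z = %.4f, p = %.4g  [%s%s]\n",
              x$I, x$expected, x$z, x$p_value, x$method,
              if (x$method == "permutation")
                sprintf(", %d shuffles", x$n_permutations) else ""))
  invisible(x)
}
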