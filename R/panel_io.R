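# Reading, validation and transformation of the balanced province x year
# indicator and covariate panels.
#
# Indicator system (per unit-year):
#   I1        initial input: per-capita health expenditure (currency, > 0)
#   M1-M3     intermediate outputs: institutions / technicians / beds per
#             thousand population (> 0)
#   F1-F5     final outputs: diagnoses, bed-utilization rate, and three
#             negative-direction outcomes (infectious-disease incidence,
#             maternal mortality, perinatal mortality) that must be
#             positivized (reciprocal) before any DEA run.

indicator_cols <- function() c("I1", "M1", "M2", "M3",
                               "F1", "F2", "F3", "F4", "F5")
covariate_cols <- function() c("pgdp", "fiscal", "urban", "edu", "depend")
negative_indicator_cols <- function() c("F3", "F4", "F5")

#' Validate and classify a long-format panel data frame
#'
#' Checks balance (every unit-year cell exactly once), numeric columns, and
#' strict positivity of every value (positivity is required both for the DEA
#' multipliers and for the reciprocal/log transforms downstream).  Rows are
#' normalized to (unit, year) order.
#'
#' @param df data.frame with columns `unit`, `year`, plus the value columns.
#' @param value_cols character vector of required value columns.
#' @param what label used in diagnostics.
#' @return the validated, reordered data.frame.
#' @keywords internal
validate_panel <- function(df, value_cols, what = "panel") {
  need <- c("unit", "year", value_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[, need, drop = FALSE]
  if (!is.numeric(df$year)) stop(sprintf("%s: 'year' must be numeric", what),
                                 call. = FALSE)
  for (cl in value_cols) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("%s: column '%s' is not numeric", what, cl), call. = FALSE)
    }
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] <= 0)
    if (length(bad)) {
      stop(sprintf(
        "%s: non-positive or non-finite value in column '%s' at unit '%s', year %d",
        what, cl, df$unit[bad[1]], as.integer(df$year[bad[1]])), call. = FALSE)
    }
  }
  units <- sort(unique(df$unit))
  years <- sort(unique(df$year))
  key <- paste(df$unit, df$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("%s: duplicate record for unit '%s', year %d", what,
                 df$unit[dup[1]], as.integer(df$year[dup[1]])), call. = FALSE)
  }
  full <- as.vector(outer(units, years, paste, sep = "\r"))
  gap <- setdiff(full, key)
  if (length(gap)) {
    g <- strsplit(gap[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("%s: unbalanced panel, missing record for unit '%s', year %s",
                 what, g[1], g[2]), call. = FALSE)
  }
  df <- df[order(df$unit, df$year), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a balanced indicator panel from CSV
#'
#' Long format, one row per unit-year, columns
#' `unit, year, I1, M1, M2, M3, F1, F2, F3, F4, F5`.  The panel is validated
#' (balanced, numeric, strictly positive) and row order is normalized to
#' (unit, year).
#'
#' @param path path to a CSV file with a single header row (UTF-8).
#' @return a data.frame of class `indicator_panel`; the attribute
#'   `positivized` is `FALSE` (raw negative-direction indicators).
#' @seealso [positivize_indicators()], [write_panel()]
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_indicator_panel(df, positivized = FALSE)
}

#' Construct an indicator panel from a data frame
#'
#' @param df data.frame in the [read_panel()] layout.
#' @param positivized whether `F3`--`F5` already hold reciprocals.
#' @return validated `indicator_panel`.
#' @export
as_indicator_panel <- function(df, positivized = FALSE) {
  df <- validate_panel(as.data.frame(df), indicator_cols(), "indicator panel")
  structure(df, class = c("indicator_panel", "data.frame"),
            positivized = isTRUE(positivized))
}

#' Read a balanced covariate panel from CSV
#'
#' Columns `unit, year, pgdp, fiscal, urban, edu, depend`; all values must be
#' strictly positive so the log transform used in the spatial Durbin
#' regression is defined.
#'
#' @param path path to a CSV file.
#' @return data.frame of class `covariate_panel`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_covariate_panel(df)
}

#' @rdname read_covariates
#' @param df data.frame in the `read_covariates()` layout.
#' @export
as_covariate_panel <- function(df) {
  df <- validate_panel(as.data.frame(df), covariate_cols(), "covariate panel")
  structure(df, class = c("covariate_panel", "data.frame"))
}

#' Write a panel to CSV at full double precision
#'
#' Numeric values are serialized with 17 significant digits so that
#' `read_panel(write_panel(p))` reproduces `p` exactly.
#'
#' @param panel an `indicator_panel` or `covariate_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Positivize the negative-direction indicators
#'
#' Infectious-disease incidence (`F3`), maternal mortality (`F4`) and
#' perinatal mortality (`F5`) are "less is better" outcomes; they enter the
#' DEA as benefit outputs after taking reciprocals.  Values of zero are
#' rejected (reciprocal undefined), and applying the transform twice is an
#' error rather than a silent round trip.
#'
#' No rescaling is applied after the reciprocal: efficiency under the
#' constant-returns multiplier models is invariant to per-column rescaling,
#' so the raw reciprocals are sufficient.
#'
#' @param panel an `indicator_panel` with `positivized = FALSE`.
#' @return the panel with `F3`--`F5` replaced by reciprocals and
#'   `positivized = TRUE`.
#' @export
positivize_indicators <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (isTRUE(attr(panel, "positivized"))) {
    stop("panel is already positivized; applying the reciprocal twice would silently undo it",
         call. = FALSE)
  }
  for (cl in negative_indicator_cols()) {
    bad <- which(panel[[cl]] <= 0)
    if (length(bad)) {
      stop(sprintf(
        "reciprocal undefined: %s is %g at unit '%s', year %d",
        cl, panel[[cl]][bad[1]], panel$unit[bad[1]],
        as.integer(panel$year[bad[1]])), call. = FALSE)
    }
    panel[[cl]] <- 1 / panel[[cl]]
  }
  attr(panel, "positivized") <- TRUE
  panel
}

#' Descriptive statistics of a numeric vector
#'
#' Count, mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum -- the summary layout used for panel QC and for provincial
#' efficiency averages.
#'
#' @param values nonempty numeric vector.
#' @return data.frame with columns `n`, `mean`, `sd`, `min`, `max`.
#' @export
compute_descriptives <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty collection", call. = FALSE)
  if (anyNA(values)) stop("missing values in collection", call. = FALSE)
  data.frame(n = length(values), mean = mean(values),
             sd = if (length(values) > 1) stats::sd(values) else NA_real_,
             min = min(values), max = max(values))
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("Indicator panel: %d units x %d years (%d records), %s\n",
              length(unique(x$unit)), length(unique(x$year)), nrow(x),
              if (isTRUE(attr(x, "positivized")))
                "positivized (F3-F5 are reciprocals)" else "raw"))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
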