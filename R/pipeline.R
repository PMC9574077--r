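# Study orchestration: yearly DEA -> provincial averages -> regional trends
# -> natural-breaks classification -> yearly Moran table -> SDM with effects.

#' Regional and national mean efficiencies per year
#'
#' Unweighted arithmetic means of overall, stage-1 and stage-2 efficiency
#' per region and year, plus a national row per year.
#'
#' @param scores a `dea_scores` table (or data.frame with `unit`, `year`,
#'   `overall`, `stage1`, `stage2`).
#' @param grouping data.frame mapping `unit` to `region` (e.g.
#'   [china_regions()]).
#' @return data.frame with columns `region`, `year`, `overall`, `stage1`,
#'   `stage2`; region `"national"` aggregates all units.
#' @export
regional_trends <- function(scores, grouping = china_regions()) {
  sc <- as.data.frame(scores)
  unmapped <- setdiff(unique(sc$unit), grouping$unit)
  if (length(unmapped)) {
    stop(sprintf("unit(s) not mapped to a region: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  sc$region <- grouping$region[match(sc$unit, grouping$unit)]
  agg <- function(d, tag) {
    out <- stats::aggregate(d[, c("overall", "stage1", "stage2")],
                            by = list(region = tag, year = d$year), mean)
    out
  }
  rbind(agg(sc, sc$region), agg(sc, rep("national", nrow(sc))))
}

#' Fisher-Jenks natural-breaks classification
#'
#' Optimal partition of a numeric vector into `k` contiguous (in value)
#' classes minimizing the total within-class sum of squared deviations,
#' found by dynamic programming -- the exact optimum, not the iterative
#' heuristic.
#'
#' @param values numeric vector (length >= k).
#' @param k number of classes (>= 2); must not exceed the number of
#'   distinct values.
#' @return list with `breaks` (the k - 1 upper boundaries of the first
#'   k - 1 classes, strictly increasing), `classes` (integer class of every
#'   input value, 1 = lowest), and `withinss` (the minimized criterion).
#' @export
jenks_breaks <- function(values, k) {
  x <- as.numeric(values)
  stopifnot(k >= 2, length(x) >= k)
  if (anyNA(x)) stop("missing values", call. = FALSE)
  if (length(unique(x)) < k) {
    stop(sprintf("cannot form %d classes from %d distinct values", k,
                 length(unique(x))), call. = FALSE)
  }
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  # SSD of xs[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)      # D[c, j]: best cost of first j points in c classes
  P <- matrix(0L, k, n)       # split point: last class starts at P+1
  for (j in 1:n) D[1, j] <- ssd(1, j)
  for (cc in 2:k) {
    for (j in cc:n) {
      best <- Inf; arg <- 0L
      for (i in (cc - 1):(j - 1)) {
        v <- D[cc - 1, i] + ssd(i + 1, j)
        if (v < best) { best <- v; arg <- i }
      }
      D[cc, j] <- best; P[cc, j] <- arg
    }
  }
  # reconstruct class boundaries on the sorted data
  bounds <- integer(k)        # index of last element of each class
  j <- n
  for (cc in k:1) { bounds[cc] <- j; j <- if (cc > 1) P[cc, j] else 0L }
  cls_sorted <- rep(seq_len(k), diff(c(0L, bounds)))
  classes <- integer(n)
  classes[ord] <- cls_sorted
  list(breaks = xs[bounds[-k]], classes = classes, withinss = D[k, n])
}

#' Five-class efficiency map table
#'
#' Classifies per-unit efficiency values into the five conventional levels
#' (low, lower, medium, higher, high) with Fisher-Jenks natural breaks.
#'
#' @param values numeric efficiency values.
#' @param units unit labels aligned with `values`.
#' @param k number of classes (default 5).
#' @param labels class labels, lowest first.
#' @return data.frame `unit`, `value`, `class` (ordered factor), with the
#'   break points as attribute `"breaks"`.
#' @export
classify_map_table <- function(values, units, k = 5,
                               labels = c("low", "lower", "medium",
                                          "higher", "high")) {
  stopifnot(length(values) == length(units), length(labels) == k)
  jb <- jenks_breaks(values, k)
  out <- data.frame(unit = units, value = values,
                    class = factor(labels[jb$classes], levels = labels,
                                   ordered = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "breaks") <- jb$breaks
  out
}

#' Yearly global Moran's I table
#'
#' One Moran test per year on a cross-section of efficiency scores; years
#' with constant scores (undefined statistic) are flagged with `NA` rather
#' than aborting the table.
#'
#' @param scores a `dea_scores`-layout data.frame.
#' @param weights a `spatial_weights` covering the score units.
#' @param column which efficiency column to test (default `"overall"`).
#' @param method,n_permutations,seed passed to [moran_inference()]; the
#'   seed is advanced deterministically per year.
#' @return data.frame `year`, `I`, `expected`, `z`, `p_value`, `defined`.
#' @export
yearly_moran_table <- function(scores, weights, column = "overall",
                               method = "permutation",
                               n_permutations = 999, seed = NULL) {
  sc <- as.data.frame(scores)
  years <- sort(unique(sc$year))
  rows <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    sub <- sc[sc$year == yr, ]
    x <- sub[[column]][match(weights$units, sub$unit)]
    if (anyNA(x)) stop(sprintf("year %s: scores missing for some units", yr),
                       call. = FALSE)
    res <- tryCatch(
      moran_inference(x, weights, method = method,
                      n_permutations = n_permutations,
                      seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) NULL)
    if (is.null(res)) {
      data.frame(year = yr, I = NA_real_, expected = NA_real_, z = NA_real_,
                 p_value = NA_real_, defined = FALSE)
    } else {
      data.frame(year = yr, I = res$I, expected = res$expected, z = res$z,
                 p_value = res$p_value, defined = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Provincial average efficiency table with a Mean row
#'
#' Per-unit averages of the three efficiency series over all years, plus a
#' final `"Mean"` row holding the column means across units -- the layout
#' used to summarize a full study period.
#'
#' @param scores a `dea_scores` table.
#' @return data.frame `unit`, `overall`, `stage1`, `stage2`.
#' @export
provincial_averages <- function(scores) {
  sc <- as.data.frame(scores)
  avg <- stats::aggregate(sc[, c("overall", "stage1", "stage2")],
                          by = list(unit = sc$unit), mean)
  rbind(avg, data.frame(unit = "Mean", overall = mean(avg$overall),
                        stage1 = mean(avg$stage1),
                        stage2 = mean(avg$stage2)))
}

#' Run the full efficiency-and-spillover study
#'
#' Orchestrates the pipeline: read and positivize the indicator panel,
#' score every year with the relational two-stage DEA, build the
#' provincial-average and regional-trend tables, classify the first and
#' last year's efficiency into five natural-breaks levels, compute the
#' yearly Moran table, and fit the two-way fixed-effects SDM with its
#' specification battery and effect decomposition.  All outputs are
#' written as CSV (tables) and JSON (tests, run log) into `out_dir`; the
#' run log records every setting and seed so a rerun reproduces the bundle.
#'
#' @param config list (or path to a YAML file) with entries:
#'   `panel`, `covariates` (CSV paths), `adjacency` (CSV path with
#'   `from`,`to` columns, optional -- defaults to the packaged province
#'   contiguity when the panel units are the 31 provinces), `out_dir`,
#'   `seed`, and optional sublists `dea` (`epsilon`, `priority`),
#'   `moran` (`method`, `n_permutations`), `sdm` (`n_draws`), and
#'   `regions` (path to a `unit,region` CSV).
#' @return invisibly, a list with every computed artifact.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$panel), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dea_cfg <- do.call(dea_config, c(list(), config$dea))
  moran_method <- if (is.null(config$moran$method)) "permutation"
                  else config$moran$method
  n_perm <- if (is.null(config$moran$n_permutations)) 999
            else config$moran$n_permutations
  n_draws <- if (is.null(config$sdm$n_draws)) 1000 else config$sdm$n_draws
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- read_panel(config$panel)
  units <- sort(unique(panel$unit))
  grouping <- if (!is.null(config$regions)) {
    utils::read.csv(config$regions, stringsAsFactors = FALSE)
  } else china_regions()
  adjacency <- if (!is.null(config$adjacency)) {
    utils::read.csv(config$adjacency, stringsAsFactors = FALSE)
  } else china_adjacency()
  weights <- build_weights(adjacency, units)

  panel <- positivize_indicators(panel)
  scores <- run_dea_panel(panel, dea_cfg)
  prov_avg <- provincial_averages(scores)
  trends <- regional_trends(scores, grouping)
  years <- sort(unique(scores$year))
  class_first <- classify_map_table(
    scores$overall[scores$year == years[1]],
    scores$unit[scores$year == years[1]])
  class_last <- classify_map_table(
    scores$overall[scores$year == years[length(years)]],
    scores$unit[scores$year == years[length(years)]])
  moran_tab <- yearly_moran_table(scores, weights, method = moran_method,
                                  n_permutations = n_perm, seed = seed)

  artifacts <- list(scores = as.data.frame(scores),
                    provincial_averages = prov_avg,
                    regional_trends = trends,
                    classified_first = class_first,
                    classified_last = class_last,
                    moran = moran_tab)
  if (!is.null(config$covariates)) {
    covs <- read_covariates(config$covariates)
    sdat <- build_sdm_data(scores, covs, weights)
    fit <- fit_sdm(sdat)
    artifacts$sdm_coefficients <- sdm_coef_table(fit)
    artifacts$sdm_effects <- as.data.frame(
      effects_decomposition(fit, n_draws = n_draws, seed = seed))
    artifacts$sdm_tests <- rbind(lm_tests(sdat),
                                 lr_wald_tests(fit, sdat),
                                 cbind(test = "hausman", panel_hausman(sdat)))
  }

  for (nm in names(artifacts)) {
    utils::write.csv(artifacts[[nm]],
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  log_entry <- list(seed = seed, epsilon = dea_cfg$epsilon,
                    priority = dea_cfg$priority,
                    weights_standardized = weights$standardized,
                    moran_method = moran_method, n_permutations = n_perm,
                    effect_draws = n_draws,
                    years = years, n_units = length(units))
  cat(jsonlite::toJSON(log_entry, auto_unbox = TRUE),
      file = file.path(config$out_dir, "run_log.jsonl"), sep = "\n")
  invisible(artifacts)
}
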