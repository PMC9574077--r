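# Published reference tables shipped for arithmetic-consistency checks.

#' Published provincial average efficiency table
#'
#' Average overall, resource-allocation (stage 1) and service-operation
#' (stage 2) health-system efficiencies of the 31 Chinese provinces over
#' 2009--2020, as published.  Used to exercise the pipeline's table
#' arithmetic (column means, product-identity checks); the underlying
#' yearbook panel is not deposited, so these averages are inputs, not
#' outputs, of this package.
#'
#' @return data.frame with columns `unit`, `overall`, `stage1`, `stage2`
#'   (31 rows).
#' @export
reference_efficiency_table <- function() {
  utils::read.csv(system.file("extdata", "provincial_efficiency_averages.csv",
                              package = "healthdea"),
                  stringsAsFactors = FALSE)
}

#' Published SDM effect-decomposition components
#'
#' Direct and indirect (spillover) effects of the five log covariates on
#' provincial health-system efficiency, as published, with the printed
#' totals; shipped to exercise the additivity contract of
#' [effects_decomposition()].
#'
#' @return data.frame with columns `variable`, `direct`, `indirect`,
#'   `total`.
#' @export
reference_effects_table <- function() {
  utils::read.csv(system.file("extdata", "sdm_effects_reference.csv",
                              package = "healthdea"),
                  stringsAsFactors = FALSE)
}
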