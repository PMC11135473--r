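#' Published benchmark MSE / relative-efficiency tables
#'
#' Per-environment test mean squared errors and relative efficiencies
#' reported for three multi-environment genomic prediction datasets
#' (Japonica rice, USP maize, G2F 2016 maize) under four predictors and the
#' NoEC/EC/FE environment-kernel strategies, including the printed `"Across"`
#' rows. These cells serve as worked examples for the relative-efficiency and
#' Across-aggregation arithmetic.
#'
#' @return Data frame with columns `dataset`, `predictor`, `trait`, `env`,
#'   `mse_noec`, `mse_ec`, `mse_fe`, `re_noec_vs_ec`, `re_ec_vs_fe`,
#'   `re_noec_vs_fe`. MSE columns are `NA` on `"Across"` rows.
#' @export
reference_re_tables <- function() {
  path <- system.file("extdata", "reference_re_tables.csv", package = "fegp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-predictor summary of relative efficiencies
#'
#' The across-dataset summary table: one row per predictor plus an
#' `"Average"` row, for the three strategy comparisons.
#'
#' @return Data frame with columns `predictor`, `re_noec_vs_ec`,
#'   `re_ec_vs_fe`, `re_noec_vs_fe`.
#' @export
reference_summary_table <- function() {
  path <- system.file("extdata", "reference_summary_table.csv", package = "fegp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
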