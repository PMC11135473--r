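#' Read and validate a YAML run configuration
#'
#' The configuration names either the three input CSVs (`inputs:` with
#' `phenotypes`, `markers`, `covariates`) or a simulation block
#' (`simulation:` with [sim_config()] fields) — exactly one of the two — plus
#' optional `predictors`, `strategies`, `traits`, `thresholds`, `fe` (fields
#' of [fe_config()]), `mcmc` (fields of [mcmc_config()]) and `output_dir`.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulation)
  if (has_inputs == has_sim) {
    stop("config must contain exactly one of 'inputs' or 'simulation'", call. = FALSE)
  }
  if (has_inputs &&
      !all(c("phenotypes", "markers", "covariates") %in% names(cfg$inputs))) {
    stop("'inputs' must name phenotypes, markers and covariates CSVs", call. = FALSE)
  }
  valid_pred <- c("E+G", "E+G+GE", "E+G+BRR", "E+G+GE+BRR")
  if (!is.null(cfg$predictors) && !all(cfg$predictors %in% valid_pred)) {
    stop(sprintf("unknown predictor '%s'; valid: %s",
                 setdiff(cfg$predictors, valid_pred)[1L],
                 paste(valid_pred, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$strategies) && !all(cfg$strategies %in% c("NoEC", "EC", "FE"))) {
    stop("strategies must be among NoEC, EC, FE", call. = FALSE)
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sim <- function(cfg, seed = NULL) {
  args <- cfg$simulation
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

config_fe <- function(cfg) do.call(fe_config, cfg$fe %||% list())

config_mcmc <- function(cfg, seed = NULL, iters = NULL) {
  args <- cfg$mcmc %||% list()
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(iters)) {
    args$n_iter <- iters
    args$burn_in <- min(args$burn_in %||% 1000L, max(iters %/% 5L, 1L))
  }
  do.call(mcmc_config, args)
}

#' Simulate a dataset from a run configuration
#'
#' @param config Path to a YAML config with a `simulation` block, or a
#'   `run_config`.
#' @param seed Optional seed override.
#' @return Invisibly, the paths written into `output_dir`.
#' @export
cmd_simulate <- function(config, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$simulation)) {
    stop("config has no 'simulation' block", call. = FALSE)
  }
  sim <- simulate_met(config_sim(cfg, seed))
  invisible(write_simulation(sim, cfg$output_dir))
}

#' Run the full cross-validation pipeline from a configuration
#'
#' Loads (or simulates) the inputs, runs [run_cv()], and writes into
#' `output_dir`: `results.csv` (per-environment MSEs and rounded REs, plus
#' Across rows and a full-precision companion), `summary.csv` (per-predictor
#' REs averaged over traits with an Average row), `cv_log.csv` (one row per
#' predictor/trait/env/strategy with the threshold cascade outcome), and one
#' JSON selection sidecar per fold and strategy.
#'
#' @param config Path to a YAML config, or a `run_config`.
#' @param seed Optional seed override for both simulation and MCMC.
#' @param iters Optional override of the MCMC iteration count.
#' @param quiet Suppress the per-fold progress log (default `TRUE`).
#' @return Invisibly, the `cv_result`.
#' @export
cmd_run <- function(config, seed = NULL, iters = NULL, quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (!is.null(cfg$simulation)) {
    sim <- simulate_met(config_sim(cfg, seed))
    phen <- sim$phenotypes; markers <- sim$markers; covs <- sim$covariates
  } else {
    phen <- read_phenotypes(cfg$inputs$phenotypes)
    markers <- read_markers(cfg$inputs$markers)
    covs <- read_env_covariates(cfg$inputs$covariates)
  }
  res <- run_cv(phen, markers, covs,
                predictors = cfg$predictors %||% c("E+G", "E+G+GE", "E+G+BRR", "E+G+GE+BRR"),
                strategies = cfg$strategies %||% c("NoEC", "EC", "FE"),
                traits = cfg$traits,
                fe_cfg = config_fe(cfg),
                mcmc = config_mcmc(cfg, seed, iters),
                thresholds = cfg$thresholds %||% c(0.5, 0.4, 0.3))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(res, file.path(cfg$output_dir, "results.csv"))
  utils::write.csv(summarize_cv(res), file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$log, file.path(cfg$output_dir, "cv_log.csv"), row.names = FALSE)
  sel_dir <- file.path(cfg$output_dir, "selections")
  dir.create(sel_dir, showWarnings = FALSE)
  for (key in names(res$selections)) {
    write_selection(res$selections[[key]],
                    file.path(sel_dir, paste0(gsub("/", "_", key), ".json")))
  }
  if (!quiet) {
    for (i in seq_len(nrow(res$log))) {
      message(paste(unlist(res$log[i, ]), collapse = "\t"))
    }
  }
  invisible(res)
}
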