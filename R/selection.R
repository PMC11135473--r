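#' Observation-level correlation between a covariate and a trait
#'
#' Pairs every non-missing training observation with the covariate value of
#' its environment and returns the Pearson correlation. Only environments in
#' `train_envs` contribute, so the held-out environment's responses never
#' touch the selection. Constant covariates over the training environments,
#' or fewer than 3 usable observations, return `NA` (the column is excluded
#' downstream).
#'
#' @param column Named numeric vector of covariate values, names are env ids.
#' @param phen A `phenotype_table`.
#' @param trait Trait name.
#' @param train_envs Character vector of training environment ids.
#' @return Pearson correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
env_correlation <- function(column, phen, trait, train_envs) {
  stopifnot(!is.null(names(column)))
  rec <- phen[phen$trait == trait & phen$env %in% train_envs & !is.na(phen$value), ,
              drop = FALSE]
  if (nrow(rec) < 3L) return(NA_real_)
  x <- column[rec$env]
  if (max(x) - min(x) <= 0) return(NA_real_)
  if (stats::sd(rec$value) == 0) return(NA_real_)
  stats::cor(x, rec$value)
}

#' Select environmental covariates by a correlation-threshold cascade
#'
#' Computes the observation-level Pearson correlation of every covariate with
#' the trait over the training environments (all environments except
#' `test_env`), then walks the thresholds in decreasing order: the first
#' threshold at which at least one covariate reaches `|r| >=` threshold wins
#' and all covariates meeting it are selected. If no covariate reaches the
#' last threshold the selection is empty and the caller falls back to the
#' identity environment kernel (the NoEC strategy) for this fold.
#'
#' @param W An `env_covariate_table` (original or engineered).
#' @param phen A `phenotype_table`.
#' @param trait Trait name.
#' @param test_env Held-out environment id; its responses are excluded.
#' @param thresholds Strictly decreasing thresholds, default `c(0.5, 0.4, 0.3)`.
#' @return A `selection_result`: list with `selected_columns`,
#'   `threshold_used` (numeric, or `"none"`), `correlations` (named, `NA` for
#'   undefined columns) and `scaling` (per selected column, mean and sample sd
#'   over all environments).
#' @export
select_covariates <- function(W, phen, trait, test_env,
                              thresholds = c(0.5, 0.4, 0.3)) {
  stopifnot(inherits(W, "env_covariate_table"))
  if (!test_env %in% rownames(W)) {
    stop(sprintf("test environment '%s' not in covariate table", test_env), call. = FALSE)
  }
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  train_envs <- setdiff(rownames(W), test_env)
  cors <- vapply(seq_len(ncol(W)), function(i) {
    env_correlation(W[, i], phen, trait, train_envs)
  }, numeric(1))
  names(cors) <- colnames(W)
  selected <- character(0); threshold_used <- "none"
  for (th in thresholds) {
    hit <- !is.na(cors) & abs(cors) >= th
    if (any(hit)) { selected <- colnames(W)[hit]; threshold_used <- th; break }
  }
  scaling <- NULL
  if (length(selected)) {
    mu <- colMeans(W[, selected, drop = FALSE])
    sd_ <- apply(W[, selected, drop = FALSE], 2L, stats::sd)
    keep <- sd_ > 0
    if (!all(keep)) {
      warning(sprintf("dropping zero-variance selected column(s): %s",
                      paste(selected[!keep], collapse = ", ")), call. = FALSE)
      selected <- selected[keep]; mu <- mu[keep]; sd_ <- sd_[keep]
      if (!length(selected)) threshold_used <- "none"
    }
    if (length(selected)) scaling <- list(mean = mu, sd = sd_)
  }
  structure(list(selected_columns = selected, threshold_used = threshold_used,
                 correlations = cors, scaling = scaling),
            class = "selection_result")
}

#' Center and scale the selected covariates
#'
#' Standardizes each selected column by its mean and sample standard
#' deviation computed over all I environments. Covariates (unlike responses)
#' are known for the held-out environment and are needed to build its kernel
#' row, so scaling over all environments leaks no response information.
#'
#' @param W An `env_covariate_table`.
#' @param sel A `selection_result` with a non-empty selection.
#' @return I x q_sel numeric matrix of standardized covariate values.
#' @export
scale_selected <- function(W, sel) {
  stopifnot(inherits(W, "env_covariate_table"), inherits(sel, "selection_result"))
  if (!length(sel$selected_columns)) stop("empty selection; nothing to scale", call. = FALSE)
  X <- W[, sel$selected_columns, drop = FALSE]
  sweep(sweep(X, 2L, sel$scaling$mean, "-"), 2L, sel$scaling$sd, "/")
}

#' Serialize a selection result to a JSON sidecar
#'
#' @param sel A `selection_result`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(list(
    selected_columns = sel$selected_columns,
    threshold_used = sel$threshold_used,
    correlations = as.list(sel$correlations)
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
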