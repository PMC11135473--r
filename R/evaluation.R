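#' Leave-one-environment-out folds
#'
#' One fold per environment with at least one non-missing observation for the
#' trait; each such environment is the test set exactly once and all other
#' environments train. Environments with no usable observations are excluded
#' with a warning.
#'
#' @param phen A `phenotype_table`.
#' @param trait Trait name.
#' @return List of folds, each `list(test_env, train_envs)`.
#' @export
loeo_folds <- function(phen, trait) {
  rec <- phen[phen$trait == trait, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records for trait '%s'", trait), call. = FALSE)
  all_envs <- sort(unique(rec$env))
  usable <- vapply(all_envs, function(ev) {
    any(!is.na(rec$value[rec$env == ev]))
  }, logical(1))
  if (any(!usable)) {
    warning(sprintf("excluding environment(s) with no observed values: %s",
                    paste(all_envs[!usable], collapse = ", ")), call. = FALSE)
  }
  envs <- all_envs[usable]
  if (length(envs) < 2L) stop("need at least 2 environments with data", call. = FALSE)
  lapply(envs, function(ev) list(test_env = ev, train_envs = setdiff(envs, ev)))
}

#' Mean squared error
#'
#' @param observed,predicted Equal-length numeric vectors; `observed` must be
#'   non-missing.
#' @return Mean of squared differences.
#' @export
mse <- function(observed, predicted) {
  if (length(observed) == 0L) stop("mse of empty vectors", call. = FALSE)
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (anyNA(observed)) stop("observed values must be non-missing", call. = FALSE)
  mean((observed - predicted)^2)
}

#' Relative efficiency of two strategies' mean squared errors
#'
#' `RE = mse_a / mse_b`; values above 1 mean the strategy in the denominator
#' predicted better.
#'
#' @param mse_a,mse_b Test-set mean squared errors; `mse_b` must be positive.
#' @return The ratio.
#' @export
relative_efficiency <- function(mse_a, mse_b) {
  if (!is.finite(mse_b) || mse_b <= 0) stop("mse_b must be positive", call. = FALSE)
  mse_a / mse_b
}

#' Across-environment summary of relative efficiencies
#'
#' The arithmetic mean of the per-environment relative efficiencies, the
#' aggregation that fills the `"Across"` rows of the result tables.
#'
#' @param per_env_res Numeric vector of per-environment REs.
#' @return Their arithmetic mean.
#' @export
across_summary <- function(per_env_res) {
  per_env_res <- per_env_res[is.finite(per_env_res)]
  if (!length(per_env_res)) stop("no finite relative efficiencies", call. = FALSE)
  mean(per_env_res)
}

strategy_cols <- c(NoEC = "mse_noec", EC = "mse_ec", FE = "mse_fe")
re_pairs <- list(
  re_noec_vs_ec = c("NoEC", "EC"),
  re_ec_vs_fe   = c("EC", "FE"),
  re_noec_vs_fe = c("NoEC", "FE")
)

#' Leave-one-environment-out cross-validation of the prediction strategies
#'
#' For every (predictor, trait, fold, strategy): builds the strategy's
#' environment kernel (FE engineers the covariates before selection, EC
#' selects among the originals, NoEC uses the identity kernel), masks the
#' test environment's responses, fits the Bayesian multi-kernel model,
#' predicts the held-out observations and records the test MSE. Folds whose
#' covariate selection is empty fall back to the NoEC kernel (logged).
#' Relative efficiencies are computed per fold and averaged into `"Across"`
#' rows.
#'
#' @param phen A `phenotype_table`.
#' @param markers A `marker_matrix`.
#' @param covs An `env_covariate_table` of original covariates.
#' @param predictors Subset of `c("E+G","E+G+GE","E+G+BRR","E+G+GE+BRR")`.
#' @param strategies Subset of `c("NoEC","EC","FE")`.
#' @param traits Trait names; default all traits in `phen`.
#' @param fe_cfg An [fe_config()] for the FE strategy.
#' @param mcmc An [mcmc_config()]; fold f runs at seed `mcmc$seed + f`.
#' @param thresholds Correlation cascade passed to [select_covariates()].
#' @return A `cv_result` list: `rows` (per predictor/trait/env MSEs and REs),
#'   `across` (per predictor/trait Across REs), `log` (one row per
#'   predictor/trait/env/strategy with threshold and selection size),
#'   `selections` (per trait/env/strategy `selection_result`s), `predictions`
#'   (held-out predictions per `predictor/trait/env/strategy`).
#' @export
run_cv <- function(phen, markers, covs,
                   predictors = c("E+G", "E+G+GE", "E+G+BRR", "E+G+GE+BRR"),
                   strategies = c("NoEC", "EC", "FE"),
                   traits = NULL,
                   fe_cfg = fe_config(),
                   mcmc = mcmc_config(),
                   thresholds = c(0.5, 0.4, 0.3)) {
  stopifnot(inherits(phen, "phenotype_table"), inherits(markers, "marker_matrix"),
            inherits(covs, "env_covariate_table"))
  predictors <- match.arg(predictors, c("E+G", "E+G+GE", "E+G+BRR", "E+G+GE+BRR"),
                          several.ok = TRUE)
  strategies <- match.arg(strategies, c("NoEC", "EC", "FE"), several.ok = TRUE)
  if (is.null(traits)) traits <- sort(unique(phen$trait))

  G <- genomic_relationship(markers)
  W_fe <- if ("FE" %in% strategies) engineer_covariates(covs, fe_cfg) else NULL

  rows <- NULL; log_rows <- NULL; selections <- list(); predictions <- list()
  for (trait in traits) {
    d <- build_designs(phen, trait, markers, covs)
    Kg <- precompute_eigen(genotype_kernel(G, d))
    ke_noec <- precompute_eigen(env_kernel_noec(d))
    kge_noec <- if (any(grepl("GE", predictors)))
      precompute_eigen(ge_kernel(Kg, ke_noec)) else NULL
    folds <- loeo_folds(phen, trait)
    fold_mse <- array(NA_real_,
      dim = c(length(folds), length(predictors), length(strategies)),
      dimnames = list(vapply(folds, `[[`, "", "test_env"), predictors, strategies))

    for (f in seq_along(folds)) {
      test_env <- folds[[f]]$test_env
      is_test <- d$env == test_env
      y_masked <- d$y
      y_masked[is_test] <- NA_real_
      test_keys <- d$obs_keys[is_test & !is.na(d$y)]
      y_test <- d$y[is_test & !is.na(d$y)]
      if (length(test_keys) < 3L) {
        warning(sprintf("test environment %s has only %d observation(s)",
                        test_env, length(test_keys)), call. = FALSE)
      }
      mc_fold <- mcmc; mc_fold$seed <- mcmc$seed + f

      for (s in strategies) {
        fallback <- FALSE; sel <- NULL
        if (s == "NoEC") {
          ke <- ke_noec; Xb <- NULL
        } else {
          W <- if (s == "EC") covs else W_fe
          sel <- select_covariates(W, phen, trait, test_env, thresholds)
          selections[[paste(trait, test_env, s, sep = "/")]] <- sel
          if (!length(sel$selected_columns)) {
            fallback <- TRUE
            ke <- ke_noec; Xb <- NULL
          } else {
            Wsel <- scale_selected(W, sel)
            ke <- precompute_eigen(env_kernel_from_covariates(Wsel, d,
              kind = if (s == "EC") "KE_ec" else "KE_fe"))
            Xb <- Wsel[d$env, , drop = FALSE]
            rownames(Xb) <- d$obs_keys
          }
        }
        kge <- NULL
        for (p in predictors) {
          kernels <- list(E = ke, g = Kg)
          if (grepl("GE", p)) {
            if (is.null(kge)) {
              kge <- if (s == "NoEC" || fallback) kge_noec else
                precompute_eigen(ge_kernel(Kg, ke))
            }
            kernels$gE <- kge
          }
          X <- if (grepl("BRR", p)) Xb else NULL
          fit <- fit_bayes(kernels, y_masked, mc_fold, X = X)
          pred <- predict_missing(fit, test_keys)
          predictions[[paste(p, trait, test_env, s, sep = "/")]] <- pred
          fold_mse[f, p, s] <- mse(y_test, pred)
          log_rows <- rbind(log_rows, data.frame(
            predictor = p, trait = trait, env = test_env, strategy = s,
            threshold_used = if (is.null(sel)) NA_character_
                             else as.character(sel$threshold_used),
            n_selected = if (is.null(sel)) 0L else length(sel$selected_columns),
            fallback_noec = fallback, mse = fold_mse[f, p, s],
            stringsAsFactors = FALSE
          ))
        }
      }
    }

    for (p in predictors) {
      tab <- data.frame(predictor = p, trait = trait,
                        env = dimnames(fold_mse)[[1L]], stringsAsFactors = FALSE)
      for (s in strategies) tab[[strategy_cols[[s]]]] <- fold_mse[, p, s]
      for (re in names(re_pairs)) {
        pair <- re_pairs[[re]]
        if (all(pair %in% strategies)) {
          tab[[re]] <- fold_mse[, p, pair[1L]] / fold_mse[, p, pair[2L]]
        }
      }
      across <- data.frame(predictor = p, trait = trait, env = "Across",
                           stringsAsFactors = FALSE)
      for (s in strategies) across[[strategy_cols[[s]]]] <- NA_real_
      for (re in names(re_pairs)) {
        if (!is.null(tab[[re]])) across[[re]] <- across_summary(tab[[re]])
      }
      rows <- rbind(rows, cbind(tab, is_across = FALSE),
                    cbind(across, is_across = TRUE))
    }
  }
  res <- list(rows = rows[!rows$is_across, setdiff(names(rows), "is_across"), drop = FALSE],
              across = rows[rows$is_across, setdiff(names(rows), "is_across"), drop = FALSE],
              log = log_rows, selections = selections, predictions = predictions)
  rownames(res$rows) <- NULL; rownames(res$across) <- NULL
  class(res) <- "cv_result"
  res
}

#' Summarize a cv_result across traits (one row per predictor)
#'
#' Averages each predictor's Across-row REs over traits (unweighted), plus an
#' `"Average"` row over predictors.
#'
#' @param result A `cv_result`.
#' @return Data frame with one row per predictor and a final Average row.
#' @export
summarize_cv <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  ac <- result$across
  re_cols <- grep("^re_", names(ac), value = TRUE)
  out <- do.call(rbind, lapply(split(ac, ac$predictor), function(g) {
    row <- data.frame(predictor = g$predictor[1L], stringsAsFactors = FALSE)
    for (cc in re_cols) row[[cc]] <- mean(g[[cc]])
    row
  }))
  avg <- data.frame(predictor = "Average", stringsAsFactors = FALSE)
  for (cc in re_cols) avg[[cc]] <- mean(out[[cc]])
  out <- rbind(out, avg)
  rownames(out) <- NULL
  out
}
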