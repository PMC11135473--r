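#' MCMC settings for the multi-kernel Gibbs sampler
#'
#' @param n_iter Total Gibbs iterations (default 10000).
#' @param burn_in Discarded warm-up iterations (default 1000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer RNG seed; identical inputs and seed give bit-identical
#'   fits.
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-square priors
#'   on every variance component (default 5).
#' @param prior_R2 Prior proportion of variance attributed to the model terms
#'   jointly (default 0.5): each term's prior scale is set so its prior mode
#'   equals `prior_R2 * var(y) / n_terms`, and the residual prior mode equals
#'   `(1 - prior_R2) * var(y)`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in = 1000L, thin = 5L, seed = 1L,
                        prior_df = 5, prior_R2 = 0.5) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df, prior_R2 = prior_R2),
            class = "mcmc_config")
}

kernel_eigen <- function(K, tol = 1e-10) {
  pre <- attr(K, "eig")
  if (!is.null(pre)) return(pre)
  eg <- eigen(unclass(K), symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, tol)
  d <- eg$values[keep]
  # Gamma'Gamma = diag(d), u = Gamma %*% delta with delta ~ N(0, sigma_k^2 I)
  Gamma <- sweep(eg$vectors[, keep, drop = FALSE], 2L, sqrt(d), "*")
  list(Gamma = Gamma, d = d)
}

#' Precompute a kernel's eigendecomposition
#'
#' Attaches the rank-truncated eigendecomposition used by [fit_bayes()] so a
#' kernel reused across folds is decomposed once.
#'
#' @param K A `kernel_matrix`.
#' @return `K` with an `eig` attribute.
#' @export
precompute_eigen <- function(K) {
  attr(K, "eig") <- kernel_eigen(K)
  K
}

#' Fit a multi-kernel Bayesian GBLUP / ridge model by Gibbs sampling
#'
#' Model: `y = mu + sum_k u_k + X beta + e` with `u_k ~ N(0, sigma_k^2 K_k)`,
#' `beta ~ N(0, sigma_beta^2 I)` and `e ~ N(0, sigma^2 I)`. Each kernel term
#' is rotated by its eigendecomposition (eigenvalues below `1e-10 *
#' lambda_max` dropped) and sampled as independent Gaussian coefficients on
#' the scaled eigenvectors; variance components get scaled-inverse-chi-square
#' full conditionals; the ridge block `beta` is sampled jointly from its
#' Gaussian full conditional; missing responses are data-augmented (sampled
#' from `N(eta, sigma^2)` each iteration) so held-out observations take part
#' in the kernels but not in the likelihood. The intercept has a flat prior.
#'
#' @param kernels Named list of observation-level `kernel_matrix` objects
#'   sharing identical observation labels.
#' @param y Numeric response aligned with the kernels; `NA` marks
#'   observations to predict.
#' @param mcmc An [mcmc_config()].
#' @param X Optional n x q matrix of standardized covariates for the Bayesian
#'   ridge regression block.
#' @param fixed_variances Optional named numeric vector pinning variance
#'   components instead of sampling them (names among the kernel names,
#'   `"beta"`, `"resid"`); used to compare the sampler against closed-form
#'   BLUP solutions.
#' @return A `bmk_fit` list: `mu_hat`, `var_components` (posterior means of
#'   the variance hyperparameters), `var_realized` (posterior means of the
#'   sample variance of each realized effect vector), `effects` (posterior
#'   mean of each `u_k`), `beta_hat`, `y_hat` (posterior mean linear
#'   predictor for every observation), `samples_kept`, `obs_keys`,
#'   `psrf_sigma2` (split-chain potential scale reduction on the residual
#'   variance).
#' @export
fit_bayes <- function(kernels, y, mcmc = mcmc_config(), X = NULL,
                      fixed_variances = NULL) {
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  if (is.null(names(kernels)) || any(!nzchar(names(kernels)))) {
    stop("kernels must be a named list", call. = FALSE)
  }
  obs_keys <- dimnames(kernels[[1L]])[[1L]]
  n <- length(y)
  for (K in kernels) {
    if (nrow(K) != n) stop("kernel dimension does not match response length", call. = FALSE)
    if (!identical(dimnames(K)[[1L]], obs_keys)) {
      stop("kernels must share observation labels", call. = FALSE)
    }
  }
  obs <- !is.na(y)
  if (!any(obs)) stop("at least one non-missing response required", call. = FALSE)
  has_X <- !is.null(X) && ncol(X) > 0L
  if (has_X) stopifnot(nrow(X) == n)

  set.seed(mcmc$seed)
  df0 <- mcmc$prior_df
  var_y <- stats::var(y[obs])
  if (!is.finite(var_y) || var_y <= 0) var_y <- 1e-8
  n_terms <- length(kernels) + as.integer(has_X)
  mode_k <- mcmc$prior_R2 * var_y / n_terms
  S0_k <- mode_k * (df0 + 2) / df0
  S0_e <- (1 - mcmc$prior_R2) * var_y * (df0 + 2) / df0

  eigs <- lapply(kernels, kernel_eigen)
  nk <- length(kernels)
  sigma2_k <- rep(mode_k, nk); names(sigma2_k) <- names(kernels)
  sigma2_b <- mode_k
  sigma2_e <- (1 - mcmc$prior_R2) * var_y
  fix <- function(term) !is.null(fixed_variances) && term %in% names(fixed_variances)
  for (k in names(kernels)) if (fix(k)) sigma2_k[k] <- fixed_variances[[k]]
  if (fix("beta")) sigma2_b <- fixed_variances[["beta"]]
  if (fix("resid")) sigma2_e <- fixed_variances[["resid"]]

  mu <- mean(y[obs])
  y_cur <- y; y_cur[!obs] <- mu
  delta <- lapply(eigs, function(e) numeric(length(e$d)))
  u <- lapply(eigs, function(e) numeric(n))
  beta <- if (has_X) numeric(ncol(X)) else numeric(0)
  Xb <- numeric(n)
  if (has_X) XtX <- crossprod(X)
  e <- y_cur - mu

  kept <- 0L
  acc <- list(mu = 0, sigma2_k = sigma2_k * 0, sigma2_b = 0, sigma2_e = 0,
              eta = numeric(n), u = lapply(seq_len(nk), function(i) numeric(n)),
              beta = beta * 0, var_real = c(sigma2_k * 0, resid = 0))
  sigma2_e_draws <- numeric((mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin)

  for (iter in seq_len(mcmc$n_iter)) {
    # intercept (flat prior)
    epl <- e + mu
    mu <- stats::rnorm(1L, mean(epl), sqrt(sigma2_e / n))
    e <- epl - mu
    # kernel terms
    for (k in seq_len(nk)) {
      e <- e + u[[k]]
      Gam <- eigs[[k]]$Gamma; d <- eigs[[k]]$d
      rhs <- crossprod(Gam, e)[, 1L] / sigma2_e
      cvar <- 1 / (d / sigma2_e + 1 / sigma2_k[k])
      delta[[k]] <- cvar * rhs + sqrt(cvar) * stats::rnorm(length(d))
      u[[k]] <- (Gam %*% delta[[k]])[, 1L]
      e <- e - u[[k]]
      if (!fix(names(kernels)[k])) {
        sigma2_k[k] <- (df0 * S0_k + sum(delta[[k]]^2)) /
          stats::rchisq(1L, df0 + length(d))
      }
    }
    # ridge block
    if (has_X) {
      e <- e + Xb
      C <- XtX / sigma2_e
      diag(C) <- diag(C) + 1 / sigma2_b
      ch <- chol(C)
      m_b <- backsolve(ch, forwardsolve(t(ch), crossprod(X, e)[, 1L] / sigma2_e))
      beta <- m_b + backsolve(ch, stats::rnorm(ncol(X)))
      Xb <- (X %*% beta)[, 1L]
      e <- e - Xb
      if (!fix("beta")) {
        sigma2_b <- (df0 * S0_k + sum(beta^2)) / stats::rchisq(1L, df0 + ncol(X))
      }
    }
    # residual variance
    if (!fix("resid")) {
      sigma2_e <- (df0 * S0_e + sum(e^2)) / stats::rchisq(1L, n + df0)
    }
    # data augmentation for missing responses
    if (any(!obs)) {
      eta_mis <- y_cur[!obs] - e[!obs]
      y_new <- eta_mis + stats::rnorm(sum(!obs), 0, sqrt(sigma2_e))
      e[!obs] <- y_new - eta_mis
      y_cur[!obs] <- y_new
    }
    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      eta <- y_cur - e
      acc$mu <- acc$mu + mu
      acc$sigma2_k <- acc$sigma2_k + sigma2_k
      acc$sigma2_b <- acc$sigma2_b + sigma2_b
      acc$sigma2_e <- acc$sigma2_e + sigma2_e
      acc$eta <- acc$eta + eta
      for (k in seq_len(nk)) {
        acc$u[[k]] <- acc$u[[k]] + u[[k]]
        acc$var_real[k] <- acc$var_real[k] + stats::var(u[[k]])
      }
      acc$var_real["resid"] <- acc$var_real["resid"] + sigma2_e
      if (has_X) acc$beta <- acc$beta + beta
      sigma2_e_draws[kept] <- sigma2_e
    }
  }
  if (kept == 0L) stop("no samples kept; check n_iter/burn_in/thin", call. = FALSE)

  psrf <- split_chain_psrf(sigma2_e_draws)
  if (is.finite(psrf) && psrf > 1.1) {
    warning(sprintf("residual variance may not have converged (split-chain PSRF %.2f)", psrf),
            call. = FALSE)
  }
  effects <- lapply(acc$u, function(v) v / kept)
  names(effects) <- names(kernels)
  var_components <- c(acc$sigma2_k / kept, resid = acc$sigma2_e / kept)
  if (has_X) var_components <- c(var_components, beta = acc$sigma2_b / kept)
  y_hat <- acc$eta / kept
  names(y_hat) <- obs_keys
  structure(list(
    mu_hat = acc$mu / kept,
    var_components = var_components,
    var_realized = acc$var_real / kept,
    effects = effects,
    beta_hat = if (has_X) acc$beta / kept else NULL,
    y_hat = y_hat,
    samples_kept = kept,
    obs_keys = obs_keys,
    missing = !obs,
    psrf_sigma2 = psrf
  ), class = "bmk_fit")
}

split_chain_psrf <- function(draws) {
  m <- length(draws) %/% 2L
  if (m < 10L) return(NA_real_)
  chains <- cbind(draws[seq_len(m)], draws[m + seq_len(m)])
  W <- mean(apply(chains, 2L, stats::var))
  B <- m * stats::var(colMeans(chains))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Predictions for selected observations
#'
#' @param fit A `bmk_fit`.
#' @param obs_keys Observation keys (`"env:geno"`) to extract.
#' @return Named numeric vector of posterior-mean predictions.
#' @export
predict_missing <- function(fit, obs_keys) {
  stopifnot(inherits(fit, "bmk_fit"))
  unknown <- setdiff(obs_keys, fit$obs_keys)
  if (length(unknown)) {
    stop(sprintf("unknown observation key %s", unknown[1L]), call. = FALSE)
  }
  fit$y_hat[obs_keys]
}

#' Variance components and line-mean heritability per trait
#'
#' Summarizes full-data fits of the environment + genotype + interaction
#' model (no covariates) into the components table: interaction
#' (`Env:Line`), genotype (`Line`), environment (`Env`) and `Residual`
#' variances, with line-mean heritability `h2 = var_g / (var_g + var_ge /
#' n_env_mean + var_resid / n_env_mean)` and the residual coefficient of
#' variation `CV = sd(residual) / mean(y)`. Component variances are the
#' posterior means of the realized (observation-level) variance of each
#' effect vector.
#'
#' @param fits Named list (trait -> `bmk_fit`) from full-data fits with
#'   kernels named `E`, `g`, `gE` and no missing responses.
#' @param phen The `phenotype_table` the fits used (for `mean(y)` and the
#'   mean number of environments per line).
#' @return Data frame with columns `component`, `VarComp`, `trait`,
#'   `heritability`, `CV`, `n_Env`.
#' @export
variance_report <- function(fits, phen) {
  stopifnot(is.list(fits), inherits(phen, "phenotype_table"))
  out <- NULL
  for (trait in names(fits)) {
    fit <- fits[[trait]]
    stopifnot(inherits(fit, "bmk_fit"))
    if (any(fit$missing)) {
      stop("variance_report requires fits on complete data (no missing responses)",
           call. = FALSE)
    }
    if (!all(c("E", "g", "gE") %in% names(fit$effects))) {
      stop("variance_report requires kernels named E, g and gE", call. = FALSE)
    }
    rec <- phen[phen$trait == trait & !is.na(phen$value), , drop = FALSE]
    n_env_mean <- mean(tapply(rec$env, rec$geno, function(e) length(unique(e))))
    v <- fit$var_realized
    h2 <- heritability(v[["g"]], v[["gE"]], v[["resid"]], n_env_mean)
    cv <- sqrt(v[["resid"]]) / mean(rec$value)
    out <- rbind(out, data.frame(
      component = c("Env:Line", "Line", "Env", "Residual"),
      VarComp = c(v[["gE"]], v[["g"]], v[["E"]], v[["resid"]]),
      trait = trait, heritability = h2, CV = cv, n_Env = n_env_mean,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Line-mean heritability
#'
#' `h2 = var_g / (var_g + var_ge / n_env_mean + var_resid / n_env_mean)`.
#'
#' @param var_g,var_ge,var_resid Genotype, interaction and residual variances.
#' @param n_env_mean Mean number of environments per line.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(var_g, var_ge, var_resid, n_env_mean) {
  var_g / (var_g + var_ge / n_env_mean + var_resid / n_env_mean)
}
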