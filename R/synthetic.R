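#' Configuration for the synthetic multi-environment trial generator
#'
#' Defaults emulate a small maize-trial layout: 4 environments of 100
#' genotypes each, ~1000 SNP markers, and 20 per-environment covariates, with
#' unit environment/genotype variances, half-unit interaction variance and
#' unit residual variance.
#'
#' @param n_geno,n_env,n_markers,n_cov Dimensions of the simulated trial.
#' @param var_env,var_geno,var_ge,var_resid Variance of the environment main
#'   effect, additive genotype effect, genotype-by-environment effect and
#'   residual.
#' @param env_signal How environment effects relate to the covariates:
#'   `"linear"` (a linear combination of the first `n_informative_cov`
#'   covariates), `"product"` (the product of the first two informative
#'   covariates — representable by pairwise feature engineering but not by
#'   any single original covariate), or `"none"` (independent of all
#'   covariates).
#' @param n_informative_cov Number of covariates driving the signal.
#' @param missing_fraction Fraction of (environment, genotype) cells removed
#'   to create an unbalanced design, in `[0, 1)`.
#' @param mu Population mean of the trait.
#' @param trait Trait name used in the phenotype table.
#' @param seed Integer seed; identical configs give identical datasets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_geno = 100L, n_env = 4L, n_markers = 1000L, n_cov = 20L,
                       var_env = 1, var_geno = 1, var_ge = 0.5, var_resid = 1,
                       env_signal = c("linear", "product", "none"),
                       n_informative_cov = 2L, missing_fraction = 0,
                       mu = 10, trait = "Y", seed = 1L) {
  env_signal <- match.arg(env_signal)
  if (n_informative_cov > n_cov) stop("n_informative_cov > n_cov", call. = FALSE)
  if (env_signal == "product" && n_informative_cov < 2L) {
    stop("product signal needs at least 2 informative covariates", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  }
  if (all(c(var_env, var_geno, var_ge, var_resid) <= 0)) {
    stop("at least one variance must be positive", call. = FALSE)
  }
  if (n_env < 2L || n_geno < 2L || n_markers < 1L || n_cov < 1L) {
    stop("invalid dimensions", call. = FALSE)
  }
  structure(list(n_geno = as.integer(n_geno), n_env = as.integer(n_env),
                 n_markers = as.integer(n_markers), n_cov = as.integer(n_cov),
                 var_env = var_env, var_geno = var_geno, var_ge = var_ge,
                 var_resid = var_resid, env_signal = env_signal,
                 n_informative_cov = as.integer(n_informative_cov),
                 missing_fraction = missing_fraction, mu = mu,
                 trait = trait, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-environment trial
#'
#' Generative model: `y_ij = mu + E_i + g_j + (gE)_ij + e_ij`. Markers are
#' binomial dosages with per-marker allele frequencies uniform on
#' (0.1, 0.5); the additive genotype effect is `g = Ms %*% alpha` with
#' standardized markers and `alpha ~ N(0, var_geno / p)`. Covariates are
#' i.i.d. standard normal per environment; the environment effect is the
#' configured signal plus ~10%-variance noise, centered and rescaled so its
#' sample variance equals `var_env`. Interaction and residual effects are
#' i.i.d. normal. A `missing_fraction` of cells is removed at random.
#'
#' @param cfg A [sim_config()].
#' @return List with `phenotypes` (`phenotype_table`), `markers`
#'   (`marker_matrix`), `covariates` (`env_covariate_table`) and `truth`
#'   (realized effects, marker weights and the observation-level realized
#'   variance of each component on the full grid).
#' @export
simulate_met <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  J <- cfg$n_geno; I <- cfg$n_env; p <- cfg$n_markers; q <- cfg$n_cov
  geno_ids <- sprintf("G%03d", seq_len(J))
  env_ids <- sprintf("E%02d", seq_len(I))

  freq <- stats::runif(p, 0.1, 0.5)
  M <- vapply(freq, function(f) stats::rbinom(J, 2L, f), numeric(J))
  for (m in seq_len(p)) {  # resample the rare monomorphic column
    tries <- 0L
    while (max(M[, m]) == min(M[, m]) && tries < 50L) {
      M[, m] <- stats::rbinom(J, 2L, freq[m]); tries <- tries + 1L
    }
  }
  dimnames(M) <- list(geno_ids, sprintf("m%04d", seq_len(p)))

  Ms <- scale(M)
  alpha <- stats::rnorm(p, 0, sqrt(cfg$var_geno / p))
  g <- as.numeric(Ms %*% alpha)

  W <- matrix(stats::rnorm(I * q), I, q,
              dimnames = list(env_ids, sprintf("cov%02d", seq_len(q))))
  k <- cfg$n_informative_cov
  signal <- switch(cfg$env_signal,
    linear  = rowSums(W[, seq_len(max(k, 1L)), drop = FALSE]) / sqrt(max(k, 1L)),
    product = W[, 1L] * W[, 2L],
    none    = stats::rnorm(I))
  E <- if (cfg$var_env > 0) {
    raw <- signal + stats::rnorm(I, 0, stats::sd(signal) / 3)
    (raw - mean(raw)) / stats::sd(raw) * sqrt(cfg$var_env)
  } else rep(0, I)
  names(E) <- env_ids

  gE <- matrix(stats::rnorm(J * I, 0, sqrt(cfg$var_ge)), J, I,
               dimnames = list(geno_ids, env_ids))
  eps <- matrix(stats::rnorm(J * I, 0, sqrt(cfg$var_resid)), J, I)
  Y <- cfg$mu + outer(g, E, "+") + gE + eps

  rec <- data.frame(
    env = rep(env_ids, each = J), geno = rep(geno_ids, I),
    trait = cfg$trait, value = as.numeric(Y), stringsAsFactors = FALSE
  )
  if (cfg$missing_fraction > 0) {
    drop_n <- floor(cfg$missing_fraction * nrow(rec))
    if (drop_n > 0L) rec <- rec[-sample.int(nrow(rec), drop_n), , drop = FALSE]
  }

  truth <- list(
    mu = cfg$mu, alpha = alpha, g = stats::setNames(g, geno_ids), E = E, gE = gE,
    var_targets = c(env = cfg$var_env, geno = cfg$var_geno,
                    ge = cfg$var_ge, resid = cfg$var_resid),
    var_realized = c(env = stats::var(rep(E, each = J)),
                     geno = stats::var(rep(g, I)),
                     ge = stats::var(as.numeric(gE)),
                     resid = stats::var(as.numeric(eps)))
  )
  list(phenotypes = phenotype_table(rec),
       markers = marker_matrix(M),
       covariates = env_covariate_table(W),
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the three input CSVs (phenotypes, markers, covariates) plus a
#' `truth.json` with the realized effects and variance targets.
#'
#' @param sim Output of [simulate_met()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("phenotypes.csv", "markers.csv", "covariates.csv",
                            "truth.json"))
  # %.17g keeps the write/read round trip exact to the last bit
  ph <- as.data.frame(unclass(sim$phenotypes))
  ph$value <- ifelse(is.na(ph$value), "", sprintf("%.17g", ph$value))
  utils::write.csv(ph, paths[1L], row.names = FALSE)
  mk <- data.frame(geno = rownames(sim$markers),
                   as.data.frame(unclass(sim$markers)), check.names = FALSE)
  utils::write.csv(mk, paths[2L], row.names = FALSE)
  cvm <- unclass(sim$covariates)
  cv <- data.frame(env = rownames(cvm),
                   as.data.frame(apply(cvm, 2L, function(x) sprintf("%.17g", x)),
                                 check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(cv, paths[3L], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
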