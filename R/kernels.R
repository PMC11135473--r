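#' Genomic relationship matrix from marker dosages
#'
#' Centers each marker column and divides it by its sample standard
#' deviation, then computes `G = M %*% t(M) / p` with `p` the number of
#' retained markers. Monomorphic (constant) marker columns cannot be
#' standardized and are dropped with a warning, adjusting `p`.
#'
#' @param markers A `marker_matrix` (J x p dosages in 0/1/2).
#' @return A `kernel_matrix` of kind `"G"`: J x J symmetric positive
#'   semidefinite matrix with genotype ids as dimnames.
#' @export
genomic_relationship <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  M <- unclass(markers)
  sds <- apply(M, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all marker columns are constant", call. = FALSE)
  if (!all(keep)) {
    warning(sprintf("dropping %d monomorphic marker(s)", sum(!keep)), call. = FALSE)
    M <- M[, keep, drop = FALSE]; sds <- sds[keep]
  }
  Ms <- sweep(sweep(M, 2L, colMeans(M), "-"), 2L, sds, "/")
  G <- tcrossprod(Ms) / ncol(Ms)
  kernel_matrix((G + t(G)) / 2, kind = "G")
}

#' Construct a labeled kernel matrix
#'
#' @param K Symmetric numeric matrix with dimnames.
#' @param kind One of `"G"`, `"Kg"`, `"KE_noec"`, `"KE_ec"`, `"KE_fe"`, `"KGE"`.
#' @param check Run symmetry/PSD validation (default `TRUE`). Eigenvalues in
#'   `(-1e-8 * lambda_max, 0)` are treated as numerical noise; anything more
#'   negative is an error.
#' @return `K` with class `kernel_matrix` and attribute `kind`.
#' @export
kernel_matrix <- function(K, kind, check = TRUE) {
  kind <- match.arg(kind, c("G", "Kg", "KE_noec", "KE_ec", "KE_fe", "KGE"))
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (check) {
    if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K)))) {
      stop("kernel is not symmetric", call. = FALSE)
    }
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(ev, 0)
    if (min(ev) < -1e-8 * max(lmax, 1)) {
      stop(sprintf("kernel is not positive semidefinite (min eigenvalue %.3g)", min(ev)),
           call. = FALSE)
    }
  }
  attr(K, "kind") <- kind
  class(K) <- c("kernel_matrix", class(matrix()))
  K
}

#' Observation-level design matrices for one trait
#'
#' Builds the genotype incidence matrix `Z_g` (n x J, over all genotypes of
#' the marker matrix) and the environment incidence matrix `X_E` (n x I, over
#' the environments present for this trait). Rows are ordered canonically:
#' by sorted environment id, then by marker-matrix genotype order. Records
#' with a missing response are kept — they are the prediction targets.
#'
#' @param phen A `phenotype_table`.
#' @param trait Trait name.
#' @param markers A `marker_matrix`.
#' @param covs An `env_covariate_table` (used to validate env ids).
#' @return A `design_matrices` list: `Z_g`, `X_E`, `obs_keys` (`"env:geno"`),
#'   `env`, `geno`, `y` (response with `NA` for missing).
#' @export
build_designs <- function(phen, trait, markers, covs) {
  stopifnot(inherits(phen, "phenotype_table"), inherits(markers, "marker_matrix"),
            inherits(covs, "env_covariate_table"))
  rec <- phen[phen$trait == trait, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records for trait '%s'", trait), call. = FALSE)
  unknown_g <- setdiff(unique(rec$geno), rownames(markers))
  if (length(unknown_g)) {
    stop(sprintf("unknown genotype %s", unknown_g[1L]), call. = FALSE)
  }
  unknown_e <- setdiff(unique(rec$env), rownames(covs))
  if (length(unknown_e)) {
    stop(sprintf("unknown environment %s", unknown_e[1L]), call. = FALSE)
  }
  genos <- rownames(markers)
  envs <- sort(unique(rec$env))
  rec <- rec[order(match(rec$env, envs), match(rec$geno, genos)), , drop = FALSE]
  n <- nrow(rec)
  Z_g <- matrix(0, n, length(genos), dimnames = list(NULL, genos))
  Z_g[cbind(seq_len(n), match(rec$geno, genos))] <- 1
  X_E <- matrix(0, n, length(envs), dimnames = list(NULL, envs))
  X_E[cbind(seq_len(n), match(rec$env, envs))] <- 1
  keys <- paste(rec$env, rec$geno, sep = ":")
  rownames(Z_g) <- keys; rownames(X_E) <- keys
  structure(list(Z_g = Z_g, X_E = X_E, obs_keys = keys,
                 env = rec$env, geno = rec$geno, y = rec$value),
            class = "design_matrices")
}

#' Identity-based environment kernel (NoEC)
#'
#' `K_E = X_E %*% t(X_E) / I`: two observations have covariance `1/I` when
#' they share an environment and 0 otherwise. This is the environment kernel
#' used when no environmental covariates are available or selected.
#'
#' @param d A `design_matrices`.
#' @return An n x n `kernel_matrix` of kind `"KE_noec"`.
#' @export
env_kernel_noec <- function(d) {
  stopifnot(inherits(d, "design_matrices"))
  I <- ncol(d$X_E)
  if (I < 2L) stop("at least 2 environments required", call. = FALSE)
  K <- tcrossprod(d$X_E) / I
  dimnames(K) <- list(d$obs_keys, d$obs_keys)
  kernel_matrix(K, kind = "KE_noec", check = FALSE)
}

#' Environment kernel from standardized covariates
#'
#' Builds the I x I linear covariate kernel `K_EC = W %*% t(W) / q_sel` from
#' the standardized selected covariates, then expands it to observation level
#' as `X_E %*% K_EC %*% t(X_E) / I`. The `q_sel` divisor mirrors the marker
#' count divisor of the genomic relationship matrix.
#'
#' @param Wsel I x q_sel matrix of standardized selected covariates (rows
#'   named by env id, in the order of `d$X_E` columns).
#' @param d A `design_matrices`.
#' @param kind `"KE_ec"` (selected original covariates) or `"KE_fe"`
#'   (selected engineered covariates).
#' @return An n x n `kernel_matrix`.
#' @export
env_kernel_from_covariates <- function(Wsel, d, kind = c("KE_ec", "KE_fe")) {
  kind <- match.arg(kind)
  stopifnot(inherits(d, "design_matrices"), is.matrix(Wsel))
  if (ncol(Wsel) == 0L) {
    stop("no covariates selected; fall back to env_kernel_noec()", call. = FALSE)
  }
  envs <- colnames(d$X_E)
  if (!all(envs %in% rownames(Wsel))) {
    stop("covariate matrix missing rows for some environments", call. = FALSE)
  }
  Wsel <- Wsel[envs, , drop = FALSE]
  K_EC <- tcrossprod(Wsel) / ncol(Wsel)
  I <- ncol(d$X_E)
  K <- d$X_E %*% K_EC %*% t(d$X_E) / I
  K <- (K + t(K)) / 2
  dimnames(K) <- list(d$obs_keys, d$obs_keys)
  kernel_matrix(K, kind = kind, check = FALSE)
}

#' Expand the genomic relationship to observation level
#'
#' `K_g = Z_g %*% G %*% t(Z_g)`: entry (a, b) equals `G[geno(a), geno(b)]`.
#'
#' @param g A `kernel_matrix` of kind `"G"`.
#' @param d A `design_matrices`.
#' @return An n x n `kernel_matrix` of kind `"Kg"`.
#' @export
genotype_kernel <- function(g, d) {
  stopifnot(inherits(g, "kernel_matrix"), inherits(d, "design_matrices"))
  if (ncol(d$Z_g) != nrow(g)) stop("G dimension does not match Z_g", call. = FALSE)
  K <- d$Z_g %*% unclass(g) %*% t(d$Z_g)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(d$obs_keys, d$obs_keys)
  kernel_matrix(K, kind = "Kg", check = FALSE)
}

#' Hadamard genotype-by-environment kernel
#'
#' Entrywise product of the observation-level genotype and environment
#' kernels; positive semidefinite by the Schur product theorem.
#'
#' @param kg,ke Observation-level `kernel_matrix` objects on identical labels.
#' @return An n x n `kernel_matrix` of kind `"KGE"`.
#' @export
ge_kernel <- function(kg, ke) {
  stopifnot(inherits(kg, "kernel_matrix"), inherits(ke, "kernel_matrix"))
  if (!identical(dimnames(kg)[[1L]], dimnames(ke)[[1L]])) {
    stop("kernel labels do not match", call. = FALSE)
  }
  K <- unclass(kg) * unclass(ke)
  kernel_matrix(K, kind = "KGE", check = FALSE)
}
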