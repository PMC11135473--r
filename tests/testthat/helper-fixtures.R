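# Fixtures are built in code; nothing is read from disk except through the
# package's own readers on files the helpers write to tempdir().

write_tmp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

tiny_phen <- function() {
  phenotype_table(data.frame(
    env = c("E1", "E1", "E2", "E2"),
    geno = c("G1", "G2", "G1", "G2"),
    trait = "GY",
    value = c(1, 2, 3, 4),
    stringsAsFactors = FALSE
  ))
}

tiny_markers <- function() {
  marker_matrix(matrix(c(0, 2, 1, 2, 0, 1), nrow = 3,
                       dimnames = list(c("G1", "G2", "G3"), c("m1", "m2"))))
}

rand_cov_table <- function(q, I, seed, positive = FALSE) {
  set.seed(seed)
  W <- matrix(stats::rnorm(I * q), I, q,
              dimnames = list(sprintf("E%02d", seq_len(I)),
                              sprintf("x%02d", seq_len(q))))
  if (positive) W <- abs(W) + 0.5
  env_covariate_table(W)
}

# Brute-force enumerator of the engineered column count, independent of the
# implementation's bookkeeping.
fe_count_oracle <- function(W, cfg) {
  q <- ncol(W)
  tol <- cfg$zero_tolerance
  n_pair <- 0L
  if (q >= 2L) {
    for (i in seq_len(q - 1L)) for (j in seq.int(i + 1L, q)) {
      for (op in cfg$pairwise_ops) {
        if (op == "div" && min(abs(W[, j])) <= tol) next
        n_pair <- n_pair + 1L
      }
    }
  }
  n_un <- 0L
  for (i in seq_len(q)) {
    x <- W[, i]
    for (op in cfg$unary_ops) {
      n_un <- n_un + switch(op,
        square = 1L,
        inverse = if (min(abs(x)) > tol) 1L else 0L,
        sqrt = if (min(x) > 0) 1L else 0L,
        log = if (min(x) > 0) 1L else 0L,
        boxcox = if (min(x) > 0) length(cfg$boxcox_lambdas) else 0L)
    }
  }
  q + n_pair + n_un
}

# Balanced phenotype/covariate fixture with EXACT observation-level Pearson
# correlations over the training environments. The response has zero
# within-environment noise, so the observation-level correlation equals the
# environment-level one; covariate columns are rho * m + sqrt(1-rho^2) * z
# with m the standardized env-mean response and z unit vectors orthogonal to
# m and to each other.
make_selection_fixture <- function(rhos, I_train = 5L, reps = 2L, seed = 99L) {
  stopifnot(length(rhos) <= I_train - 2L)
  set.seed(seed)
  m_raw <- seq_len(I_train)
  # the basis includes the constant vector so every column is mean-zero and
  # Pearson centering cannot perturb the designed correlations
  Q <- qr.Q(qr(cbind(1, m_raw - mean(m_raw),
                     matrix(stats::rnorm(I_train * (I_train - 2L)), I_train))))
  m <- Q[, 2L]
  cols <- vapply(seq_along(rhos), function(j) {
    rhos[j] * m + sqrt(1 - rhos[j]^2) * Q[, j + 2L]
  }, numeric(I_train))
  envs <- sprintf("T%02d", seq_len(I_train))
  test_env <- "Z99"
  W <- rbind(cols, 0)
  dimnames(W) <- list(c(envs, test_env), sprintf("x%02d", seq_along(rhos)))
  phen <- phenotype_table(data.frame(
    env = rep(c(envs, test_env), each = reps),
    geno = rep(sprintf("G%02d", seq_len(reps)), I_train + 1L),
    trait = "Y",
    value = c(rep(m, each = reps), stats::rnorm(reps)),
    stringsAsFactors = FALSE
  ))
  list(W = env_covariate_table(W), phen = phen, test_env = test_env,
       train_envs = envs)
}

# Closed-form posterior mean of each kernel effect with variances fixed and a
# flat prior on the intercept: u_k = s2_k * K_k %*% Pt %*% y with
# Pt = P - P 1 1' P / (1' P 1), P = V^-1, V = sum s2_k K_k + s2_e I.
blup_oracle <- function(kernels, s2k, s2e, y) {
  n <- length(y)
  V <- diag(s2e, n)
  for (k in seq_along(kernels)) V <- V + s2k[k] * unclass(kernels[[k]])
  P <- solve(V)
  one <- rep(1, n)
  Pone <- P %*% one
  Pt <- P - Pone %*% t(Pone) / sum(Pone)
  mu <- sum(Pone * y) / sum(Pone)
  u <- lapply(seq_along(kernels), function(k) {
    as.numeric(s2k[k] * unclass(kernels[[k]]) %*% Pt %*% y)
  })
  names(u) <- names(kernels)
  list(mu = mu, u = u)
}

# random PSD kernel with labels
rand_kernel <- function(n, seed, kind = "Kg", labels = NULL) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  K <- tcrossprod(A) / n
  if (is.null(labels)) labels <- sprintf("o%03d", seq_len(n))
  dimnames(K) <- list(labels, labels)
  kernel_matrix(K, kind)
}
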