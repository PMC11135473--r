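test_that("genomic relationship matches hand and per-marker accumulation oracles", {
  # J=2, one marker pair; sample-sd standardization gives M = ±1/sqrt(2)
  M2 <- marker_matrix(matrix(c(0, 2, 2, 0), 2,
                             dimnames = list(c("G1", "G2"), c("m1", "m2"))))
  G2 <- genomic_relationship(M2)
  expect_equal(unclass(G2)[, ], matrix(c(0.5, -0.5, -0.5, 0.5), 2,
               dimnames = list(c("G1", "G2"), c("G1", "G2"))), tolerance = 1e-12)

  expect_error(genomic_relationship(
    marker_matrix(matrix(c(1, 1, 2, 2), 2,
                         dimnames = list(c("G1", "G2"), c("m1", "m2"))))),
    "constant")

  # per-marker accumulation oracle on random instances
  for (seed in 1:4) {
    set.seed(seed)
    J <- sample(4:10, 1); p <- sample(10:50, 1)
    M <- matrix(sample(0:2, J * p, replace = TRUE), J,
                dimnames = list(sprintf("G%02d", 1:J), sprintf("m%02d", 1:p)))
    M <- M[, apply(M, 2, function(x) length(unique(x)) > 1), drop = FALSE]
    G <- genomic_relationship(marker_matrix(M))
    acc <- matrix(0, nrow(M), nrow(M))
    for (m in seq_len(ncol(M))) {
      v <- (M[, m] - mean(M[, m])) / stats::sd(M[, m])
      acc <- acc + tcrossprod(v)
    }
    expect_equal(unclass(G)[, ], acc / ncol(M), ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("mean diagonal of G is near 1 for binomial markers", {
  sim <- simulate_met(sim_config(n_geno = 200, n_env = 2, n_markers = 400,
                                 n_cov = 2, seed = 11))
  G <- genomic_relationship(sim$markers)
  expect_lt(abs(mean(diag(G)) - 1), 0.15)
})

test_that("design matrices encode incidence with canonical ordering", {
  phen <- tiny_phen()
  covs <- env_covariate_table(matrix(rnorm(4), 2, dimnames = list(c("E1", "E2"), c("a", "b"))))
  d <- build_designs(phen, "GY", tiny_markers(), covs)
  expect_equal(dim(d$Z_g), c(4L, 3L))
  expect_equal(unname(colSums(d$Z_g)), c(2, 2, 0))
  expect_equal(unname(colSums(d$X_E)), c(2, 2))
  expect_true(all(rowSums(d$Z_g) == 1), all(rowSums(d$X_E) == 1))

  unb <- phenotype_table(tiny_phen()[-4L, ])  # drop (E2, G2)
  d2 <- build_designs(unb, "GY", tiny_markers(), covs)
  expect_equal(nrow(d2$Z_g), 3L)
  expect_equal(unname(colSums(d2$X_E)), c(2, 1))

  bad <- phenotype_table(data.frame(env = c("E1", "E2"), geno = c("G1", "G9"),
                                    trait = "GY", value = 1:2))
  expect_error(build_designs(bad, "GY", tiny_markers(), covs), "unknown genotype G9")
})

test_that("identity environment kernel is block-constant at 1/I", {
  phen <- phenotype_table(data.frame(env = c("E1", "E1", "E2"),
                                     geno = c("G1", "G2", "G1"),
                                     trait = "GY", value = 1:3))
  covs <- env_covariate_table(matrix(rnorm(2), 2, dimnames = list(c("E1", "E2"), "a")))
  d <- build_designs(phen, "GY", tiny_markers(), covs)
  K <- env_kernel_noec(d)
  expect_equal(unclass(K)[, ], matrix(c(.5, .5, 0, .5, .5, 0, 0, 0, .5), 3),
               ignore_attr = TRUE)

  # permutation consistency: (Z K Z')[a, b] = K_EC[env(a), env(b)]
  sim <- simulate_met(sim_config(n_geno = 8, n_env = 4, n_markers = 20, n_cov = 3,
                                 missing_fraction = 0.2, seed = 3))
  d4 <- build_designs(sim$phenotypes, "Y", sim$markers, sim$covariates)
  K4 <- env_kernel_noec(d4)
  expect_true(all(diag(K4) == 0.25))
  for (a in sample(nrow(K4), 5)) for (b in sample(nrow(K4), 5)) {
    expect_equal(K4[a, b], if (d4$env[a] == d4$env[b]) 0.25 else 0)
  }
})

test_that("covariate environment kernel matches hand algebra and expansion rule", {
  phen <- phenotype_table(data.frame(env = c("E1", "E1", "E2"),
                                     geno = c("G1", "G2", "G1"),
                                     trait = "GY", value = 1:3))
  covs <- env_covariate_table(matrix(c(-1, 1), 2, dimnames = list(c("E1", "E2"), "w")))
  d <- build_designs(phen, "GY", tiny_markers(), covs)
  w <- matrix(c(-1, 1) / sqrt(2), 2, dimnames = list(c("E1", "E2"), "w"))
  K <- env_kernel_from_covariates(w, d)
  # K_EC = [[0.5, -0.5], [-0.5, 0.5]]; expansion divides by I = 2
  expect_equal(unclass(K)[, ], matrix(c(.25, .25, -.25, .25, .25, -.25,
                                        -.25, -.25, .25), 3), ignore_attr = TRUE)
  expect_error(env_kernel_from_covariates(w[, 0, drop = FALSE], d), "fall back")

  # expansion consistency on a random instance
  sim <- simulate_met(sim_config(n_geno = 10, n_env = 5, n_markers = 20, n_cov = 4,
                                 seed = 8))
  d5 <- build_designs(sim$phenotypes, "Y", sim$markers, sim$covariates)
  Wsel <- scale(unclass(sim$covariates))[, 1:2]
  K5 <- env_kernel_from_covariates(Wsel, d5)
  K_EC <- tcrossprod(Wsel) / 2
  for (a in sample(nrow(K5), 6)) for (b in sample(nrow(K5), 6)) {
    expect_equal(K5[a, b], K_EC[d5$env[a], d5$env[b]] / 5, tolerance = 1e-12)
  }
})

test_that("genotype kernel expands G to observation level", {
  G <- kernel_matrix(matrix(c(1, -1, -1, 1), 2,
                            dimnames = list(c("G1", "G2"), c("G1", "G2"))), "G")
  phen <- phenotype_table(data.frame(env = c("E1", "E1", "E2"),
                                     geno = c("G1", "G2", "G1"),
                                     trait = "GY", value = 1:3))
  M <- marker_matrix(matrix(c(0, 2, 1, 1), 2, dimnames = list(c("G1", "G2"), c("m1", "m2"))))
  covs <- env_covariate_table(matrix(rnorm(2), 2, dimnames = list(c("E1", "E2"), "a")))
  d <- build_designs(phen, "GY", M, covs)
  Kg <- genotype_kernel(G, d)
  expect_equal(unclass(Kg)[, ], matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3),
               ignore_attr = TRUE)

  # one observation per genotype -> Kg == G
  phen1 <- phenotype_table(data.frame(env = c("E1", "E2"), geno = c("G1", "G2"),
                                      trait = "GY", value = 1:2))
  d1 <- build_designs(phen1, "GY", M, covs)
  expect_equal(unclass(genotype_kernel(G, d1))[, ], unclass(G)[, ], ignore_attr = TRUE)
})

test_that("Hadamard GE kernel behaves as entrywise product and stays PSD", {
  ke <- rand_kernel(6, seed = 1, kind = "KE_ec")
  ones <- kernel_matrix(matrix(1, 6, 6, dimnames = dimnames(ke)), "Kg")
  expect_equal(unclass(ge_kernel(ones, ke))[, ], unclass(ke)[, ], ignore_attr = TRUE)

  zero <- kernel_matrix(matrix(0, 6, 6, dimnames = dimnames(ke)), "Kg")
  expect_true(all(ge_kernel(zero, ke) == 0))

  kg <- rand_kernel(6, seed = 2, kind = "Kg")
  prod <- ge_kernel(kg, ke)
  ev <- eigen(unclass(prod), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  mislabeled <- rand_kernel(6, seed = 3, kind = "KE_ec",
                            labels = sprintf("x%03d", 1:6))
  expect_error(ge_kernel(kg, mislabeled), "labels")
})
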