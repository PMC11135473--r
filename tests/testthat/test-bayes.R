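test_that("fits are bit-identical under a fixed seed", {
  K <- rand_kernel(20, seed = 4)
  set.seed(77); y <- rnorm(20); y[c(3, 9)] <- NA
  mc <- mcmc_config(n_iter = 400, burn_in = 100, thin = 2, seed = 5)
  f1 <- fit_bayes(list(g = K), y, mc)
  f2 <- fit_bayes(list(g = K), y, mc)
  expect_identical(f1$y_hat, f2$y_hat)
  expect_identical(f1$var_components, f2$var_components)
})

test_that("posterior means match the closed-form BLUP with fixed variances", {
  set.seed(10)
  n <- 40
  Kg <- rand_kernel(n, seed = 20, kind = "Kg")
  Ke <- rand_kernel(n, seed = 21, kind = "KE_noec", labels = dimnames(Kg)[[1]])
  y <- 1.5 + as.numeric(chol(unclass(Kg) + 1e-8 * diag(n)) %*% rnorm(n)) + rnorm(n, 0, 0.6)
  s2k <- c(g = 0.8, E = 0.4); s2e <- 0.36
  fit <- suppressWarnings(fit_bayes(list(g = Kg, E = Ke), y,
    mcmc_config(n_iter = 8000, burn_in = 1000, thin = 2, seed = 6),
    fixed_variances = c(s2k, resid = s2e)))
  oracle <- blup_oracle(list(g = Kg, E = Ke), s2k, s2e, y)
  tol <- 0.04 * sd(y)
  expect_lt(max(abs(fit$effects$g - oracle$u$g)), tol)
  expect_lt(max(abs(fit$effects$E - oracle$u$E)), tol)
  expect_lt(abs(fit$mu_hat - oracle$mu), tol)
})

test_that("a constant response collapses to its mean", {
  K <- rand_kernel(15, seed = 30)
  y <- rep(4.2, 15)
  fit <- suppressWarnings(fit_bayes(list(g = K), y,
    mcmc_config(n_iter = 800, burn_in = 200, thin = 2, seed = 7)))
  expect_equal(fit$mu_hat, 4.2, tolerance = 1e-3)
  expect_equal(unname(fit$y_hat), rep(4.2, 15), tolerance = 1e-2)
  expect_true(all(fit$var_components > 0))
})

test_that("predictions are exchangeable under observation permutation", {
  n <- 30
  K <- rand_kernel(n, seed = 40)
  set.seed(41); y <- as.numeric(chol(unclass(K) + 1e-8 * diag(n)) %*% rnorm(n)) + rnorm(n, 0, .5)
  mc <- mcmc_config(n_iter = 6000, burn_in = 1000, thin = 2, seed = 8)
  fit <- suppressWarnings(fit_bayes(list(g = K), y, mc,
                                    fixed_variances = c(g = 1, resid = 0.25)))
  perm <- sample(n)
  Kp <- kernel_matrix(unclass(K)[perm, perm], "Kg")
  fitp <- suppressWarnings(fit_bayes(list(g = Kp), y[perm], mc,
                                     fixed_variances = c(g = 1, resid = 0.25)))
  expect_lt(max(abs(fitp$y_hat[dimnames(K)[[1]]] - fit$y_hat)), 0.05 * sd(y))
})

test_that("missing responses are predicted and keyed correctly", {
  K <- rand_kernel(12, seed = 50)
  set.seed(51); y <- rnorm(12); y[c(2, 5)] <- NA
  fit <- suppressWarnings(fit_bayes(list(g = K), y,
    mcmc_config(n_iter = 600, burn_in = 150, thin = 2, seed = 9)))
  miss_keys <- fit$obs_keys[fit$missing]
  expect_length(predict_missing(fit, miss_keys), 2L)
  expect_true(all(is.finite(fit$y_hat)))
  expect_length(predict_missing(fit, character(0)), 0L)
  expect_equal(predict_missing(fit, fit$obs_keys[1]), fit$y_hat[1])
  expect_error(predict_missing(fit, "bogus"), "unknown observation key")
})

test_that("the GE kernel reduces training residuals on GE-simulated data", {
  better <- 0L
  for (seed in 1:20) {
    sim <- simulate_met(sim_config(n_geno = 20, n_env = 4, n_markers = 60, n_cov = 3,
                                   var_ge = 1.5, var_resid = 0.5, seed = seed))
    d <- build_designs(sim$phenotypes, "Y", sim$markers, sim$covariates)
    G <- genomic_relationship(sim$markers)
    Kg <- genotype_kernel(G, d); Ke <- env_kernel_noec(d)
    mc <- mcmc_config(n_iter = 500, burn_in = 150, thin = 2, seed = seed)
    f1 <- suppressWarnings(fit_bayes(list(E = Ke, g = Kg), d$y, mc))
    f2 <- suppressWarnings(fit_bayes(list(E = Ke, g = Kg, gE = ge_kernel(Kg, Ke)),
                                     d$y, mc))
    rss1 <- sum((d$y - f1$y_hat)^2)
    rss2 <- sum((d$y - f2$y_hat)^2)
    if (rss2 < rss1) better <- better + 1L
  }
  expect_lt(binom.test(better, 20, alternative = "greater")$p.value, 0.05)
})

test_that("heritability formula and variance report behave as documented", {
  expect_equal(heritability(1, 0, 0, 3), 1)
  expect_equal(heritability(1, 1, 1, 2), 0.5)

  sim <- simulate_met(sim_config(n_geno = 30, n_env = 4, n_markers = 80, n_cov = 3,
                                 seed = 13))
  d <- build_designs(sim$phenotypes, "Y", sim$markers, sim$covariates)
  G <- genomic_relationship(sim$markers)
  Kg <- genotype_kernel(G, d); Ke <- env_kernel_noec(d)
  fit <- suppressWarnings(fit_bayes(list(E = Ke, g = Kg, gE = ge_kernel(Kg, Ke)),
    d$y, mcmc_config(n_iter = 600, burn_in = 150, thin = 2, seed = 13)))
  rep_ <- variance_report(list(Y = fit), sim$phenotypes)
  expect_equal(rep_$component, c("Env:Line", "Line", "Env", "Residual"))
  expect_true(all(rep_$VarComp > 0))
  expect_true(all(rep_$heritability > 0 & rep_$heritability < 1))
  expect_equal(unique(rep_$n_Env), 4)

  y_na <- d$y; y_na[1] <- NA
  fit_na <- suppressWarnings(fit_bayes(list(E = Ke, g = Kg, gE = ge_kernel(Kg, Ke)),
    y_na, mcmc_config(n_iter = 300, burn_in = 100, thin = 2, seed = 14)))
  expect_error(variance_report(list(Y = fit_na), sim$phenotypes), "complete data")
})
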