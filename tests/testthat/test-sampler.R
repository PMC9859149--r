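test_that("with no kernels the residual-variance posterior matches the conjugate closed form", {
  set.seed(101)
  n <- 50
  y <- rnorm(n, 5, 2)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  pr <- prior_spec(df = 5, R2 = 0.5)
  fit <- run_chain(y, X, kernels = list(), priors = pr,
                   chain = chain_config(22000, 2000, 1, seed = 11))
  # flat b + scaled-inv-chi2(df, S) prior: posterior of sigma_e^2 is
  # scaled-inv-chi2(df + n - 1, (df S + SSR) / (df + n - 1))
  S0 <- var(y) * (1 - pr$R2) * (pr$df + 2) / pr$df
  ssr <- sum((y - mean(y))^2)
  post_mean <- (pr$df * S0 + ssr) / (pr$df + n - 1 - 2)
  draws <- fit$var_draws[, "sigma_e_sq"]
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse(draws))
  expect_true(all(draws > 0))
  expect_true(all(is.finite(fit$deviance_draws)))
})

test_that("the Gibbs marginals match a brute-force grid posterior on a tiny instance", {
  set.seed(202)
  n <- 8
  dos <- matrix(rbinom(n * 5, 2, 0.5), n, 5)
  dos[1, 1] <- 0L; dos[2, 1] <- 2L  # guarantee polymorphism
  G <- genotype_matrix(dos)
  K <- vanraden1(G)
  y <- rnorm(n) + drop(K$values %*% rnorm(n, 0, 0.5))
  X <- matrix(1, n, 1)
  pr <- prior_spec(df = 5, R2 = 0.5)
  fit <- run_chain(y, X, list(g = K), priors = pr,
                   chain = chain_config(21000, 1000, 1, seed = 7))
  vy <- var(y)
  S0g <- vy * pr$R2 * (pr$df + 2) / pr$df
  S0e <- vy * (1 - pr$R2) * (pr$df + 2) / pr$df
  gr <- grid_posterior_1k(y, X, K$values, df0 = pr$df, Sg = S0g, Se = S0e,
                          vg_range = vy * c(1e-3, 60),
                          ve_range = vy * c(1e-3, 60), n_grid = 160)
  expect_lt(gr$edge_mass, 1e-6)
  ks_g <- ks_grid_vs_sample(gr$vg, gr$cdf_vg, fit$var_draws[, 1])
  ks_e <- ks_grid_vs_sample(gr$ve, gr$cdf_ve, fit$var_draws[, 2])
  expect_lt(ks_g, 0.05)
  expect_lt(ks_e, 0.05)
})

test_that("heritability is recovered on data simulated at h2 = 0.5", {
  cfg <- sim_config(n_per_group = c(253, 179, 68), m = 2000,
                    target_vg1 = 0.5, target_vg2 = 0, var_e = 0.5, seed = 17)
  dat <- simulate_dataset(cfg)
  fit <- fit_sim_model(dat, 1, chain_config(6000, 1000, 5, seed = 17))
  s <- summarize_run(fit)
  h2 <- s$components$mean[s$components$parameter == "heritability"]
  expect_lt(abs(h2 - 0.5), 0.10)
})

test_that("chains are bit-reproducible under a fixed seed", {
  set.seed(1)
  dat <- simulate_dataset(sim_config(n_per_group = c(30, 20, 10), m = 200,
                                     seed = 2))
  f1 <- fit_sim_model(dat, 4, chain_config(400, 100, 2, seed = 5))
  f2 <- fit_sim_model(dat, 4, chain_config(400, 100, 2, seed = 5))
  expect_identical(f1$var_draws, f2$var_draws)
  expect_identical(f1$b_draws, f2$b_draws)
  expect_identical(f1$deviance_draws, f2$deviance_draws)
  # kept-draw count invariant
  expect_equal(nrow(f1$var_draws), (400 - 100) / 2)
})

test_that("posterior-mean breeding values lie in the column space of their kernel", {
  dat <- simulate_dataset(sim_config(n_per_group = c(30, 20, 10), m = 200,
                                     seed = 3))
  fit <- fit_sim_model(dat, 4, chain_config(600, 100, 2, seed = 9))
  G1 <- vanraden1(qc_filter(dat$genotypes)$genotypes, groups = dat$groups)
  for (role in names(fit$g_draws)) {
    K <- if (role == "common") G1 else block_kernel(G1, "per-group")
    e <- mkgblup:::eigen_kernel(K)
    g <- fit$posterior_means$g[[role]]
    proj <- e$U %*% crossprod(e$U, g)
    expect_lt(max(abs(g - proj)), 1e-6)
  }
  expect_true(all(fit$var_draws > 0))
})

test_that("dic arithmetic follows D_bar + pD with pD from the plug-in deviance", {
  d <- dic(c(10, 14), deviance_at_means = 11)
  expect_equal(d$mean_deviance, 12)
  expect_equal(d$pD, 1)
  expect_equal(d$DIC, 13)
  # degenerate chain: no posterior spread
  d0 <- dic(c(10, 10, 10), deviance_at_means = 10)
  expect_equal(d0$pD, 0)
  expect_equal(d0$DIC, d0$mean_deviance)
  expect_error(dic(5, deviance_at_means = 5), "at least 2")
})

test_that("pD measures model complexity: positive, and larger with an extra kernel", {
  for (s in 1:3) {
    dat <- simulate_dataset(sim_config(n_per_group = c(60, 42, 18), m = 500,
                                       target_vg1 = 0.5, target_vg2 = 0,
                                       seed = 300 + s))
    ch <- chain_config(1500, 300, 3, seed = 400 + s)
    d1 <- dic(fit_sim_model(dat, 1, ch))
    d4 <- dic(fit_sim_model(dat, 4, ch))
    expect_gt(d1$pD, 0)
    expect_gt(d4$pD, d1$pD)
  }
})

test_that("invalid chain settings are rejected", {
  expect_error(chain_config(1000, 1000, 10), "burn_in")
  expect_error(chain_config(1000, 100, 0), "thin")
})
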