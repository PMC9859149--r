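test_that("back-solve is linear, scales inversely with c, and inverts the projection", {
  set.seed(42)
  n <- 10; m <- 4
  dos <- matrix(rbinom(n * m, 2, 0.5), n, m)
  dos[1:2, ] <- rbind(rep(0L, m), rep(2L, m))  # ensure polymorphism
  G <- genotype_matrix(dos)
  p <- allele_frequency(G)
  Z <- centered_matrix(G, p)
  K <- vanraden1(G, p)
  expect_equal(qr(Z)$rank, m)

  # g_hat = 0 -> zero effects
  eff0 <- backsolve_snp_effects(Z, K, rep(0, n))
  expect_equal(unname(eff0[, 1]), rep(0, m))

  # projection identity: g in the marker column space returns a_true
  a_true <- c(0.5, -1, 0.25, 2)
  g <- drop(Z %*% a_true)
  eff <- backsolve_snp_effects(Z, K, g)
  expect_equal(unname(eff[, "common"]), a_true, tolerance = 1e-6)

  # doubling c halves the effects
  eff2 <- backsolve_snp_effects(Z, K, g, c = 2 * K$scaling_constant)
  expect_equal(unname(eff2[, 1]), unname(eff[, 1]) / 2, tolerance = 1e-12)
})

test_that("back-solve of a blocked kernel works per block and reconstructs GBVs", {
  dat <- simulate_dataset(sim_config(n_per_group = c(30, 24, 16), m = 60,
                                     seed = 8))
  G <- dat$genotypes
  p <- allele_frequency(G)
  Z <- centered_matrix(G, p)
  K3 <- block_kernel(vanraden1(G, p, groups = dat$groups), "per-group")
  g_hat <- drop(unclass(K3$values) %*% rnorm(nrow(G), 0, 0.3))
  eff <- backsolve_snp_effects(Z, K3, g_hat)
  expect_equal(colnames(eff), c("A", "B", "C"))
  # reconstruction: within each block, Z_k a_k ~ g_k (g lies in col space of K3)
  for (k in seq_along(dat$groups$labels)) {
    i <- dat$groups$assignment == dat$groups$labels[k]
    rec <- drop(Z[i, , drop = FALSE] %*% eff[, k])
    expect_lt(max(abs(rec - g_hat[i])) / max(abs(g_hat[i])), 1e-4)
  }
  # hy-vs-rest: merged block named by its groups
  K2 <- block_kernel(vanraden1(G, p, groups = dat$groups), "hy-vs-rest",
                     isolated_group = "C")
  eff2 <- backsolve_snp_effects(Z, K2, g_hat)
  expect_equal(colnames(eff2), c("A-B", "C"))
})

test_that("effect correlation tables have unit diagonal and detect sign flips", {
  set.seed(6)
  a <- rnorm(500)
  R <- effect_correlation_table(list(x = a, y = a, z = -a))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R["x", "y"], 1)
  expect_equal(R["x", "z"], -1)
  expect_warning(effect_correlation_table(list(x = a, flat = rep(1, 500))),
                 "zero-variance")
  expect_error(effect_correlation_table(list(x = a, y = rnorm(10))),
               "lengths")
})

test_that("specific effects of disjoint groups estimated under a null truth are uncorrelated", {
  cfg <- sim_config(n_per_group = c(76, 54, 30), m = 5000,
                    target_vg1 = 0, target_vg2 = 0.5, seed = 14)
  dat <- simulate_dataset(cfg)
  fit <- fit_sim_model(dat, 5, chain_config(2000, 400, 4, seed = 14), qc = FALSE)
  G <- dat$genotypes
  p <- allele_frequency(G)
  Z <- centered_matrix(G, p)
  K3 <- block_kernel(vanraden1(G, p, groups = dat$groups), "per-group")
  eff <- backsolve_snp_effects(Z, K3, fit$posterior_means$g$specific)
  R <- effect_correlation_table(list(eff))
  expect_lt(abs(R["A", "C"]), 0.1)
  expect_lt(abs(R["B", "C"]), 0.1)
})

test_that("spearman of a monotone transform is exactly 1", {
  set.seed(2)
  a <- rnorm(200)
  R <- effect_correlation_table(list(x = a, y = exp(a)), method = "spearman")
  expect_equal(R["x", "y"], 1)
})

test_that("gbv tables sum components and the report handles reference shifts", {
  dat <- simulate_dataset(sim_config(n_per_group = c(24, 18, 12), m = 150,
                                     seed = 4))
  fit <- fit_sim_model(dat, 4, chain_config(600, 100, 2, seed = 4))
  tb <- gbv_table(fit, groups = dat$groups)
  expect_equal(tb$gbv_total, tb$g_common + tb$g_specific, tolerance = 1e-10)

  # model compared with itself: all correlations 1
  rep1 <- gbv_report(list(m4 = tb, m4b = tb), reference_model = "m4")
  expect_true(all(abs(rep1$correlations$pearson - 1) < 1e-12))
  expect_true(all(abs(rep1$correlations$spearman - 1) < 1e-12))

  # reference-group shift on hand-built means {A:5, B:3, C:1}
  fake <- data.frame(animal_id = 1:6,
                     group = rep(c("A", "B", "C"), each = 2),
                     gbv_total = c(5, 5, 3, 3, 1, 1))
  rep2 <- gbv_report(list(m = fake), reference_group = "A")
  expect_equal(unlist(rep2$group_means[1, c("A", "B", "C")], use.names = FALSE),
               c(0, -2, -4))

  # prefecture effects exactly cancelling the mean differences -> all zeros
  pe <- list(m = c(A = 0, B = 2, C = 4))
  rep3 <- gbv_report(list(m = fake), reference_group = "A",
                     prefecture_effects = pe)
  expect_equal(unlist(rep3$group_means_plus_effects[1, c("A", "B", "C")],
                      use.names = FALSE), c(0, 0, 0))

  # animal mismatch
  fake2 <- fake; fake2$animal_id <- 7:12
  expect_error(gbv_report(list(a = fake, b = fake2)), "mismatch")
})
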