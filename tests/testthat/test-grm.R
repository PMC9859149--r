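test_that("centering subtracts twice the allele frequency", {
  G <- genotype_matrix(cbind(c(1, 2, 0), c(2, 1, 0)))
  Z <- centered_matrix(G, c(0.5, 0.1))
  expect_equal(Z[1, 1], 0)    # dosage 1 at p = 0.5
  expect_equal(Z[2, 1], 1)    # dosage 2 at p = 0.5
  expect_equal(Z[3, 2], -0.2) # dosage 0 at p = 0.1
  expect_error(centered_matrix(G, c(0.5)), "dimension")
})

test_that("vanraden1 matches the one-SNP hand case and degenerate cases", {
  # one SNP, dosages (0, 2): p estimated as 0.5, c = 0.5, Z = (-1, 1)
  K <- vanraden1(genotype_matrix(cbind(c(0L, 2L))))
  expect_equal(unname(K$values), rbind(c(2, -2), c(-2, 2)))
  expect_equal(K$scaling_constant, 0.5)

  # all animals heterozygous at p = 0.5: fully centered, kernel of zeros
  G0 <- genotype_matrix(matrix(1L, 3, 2))
  K0 <- vanraden1(G0, p = c(0.5, 0.5))
  expect_equal(unname(K0$values), matrix(0, 3, 3))
  expect_equal(K0$scaling_constant, 1)

  expect_error(vanraden1(G0, p = c(0, 1)), "monomorphic")
})

test_that("vanraden1 kernels are symmetric with zero row sums under sample frequencies", {
  set.seed(21)
  dat <- simulate_genotypes(sim_config(n_per_group = c(40, 30, 20), m = 400,
                                       seed = 21))
  K <- vanraden1(dat$genotypes)
  expect_lt(max(abs(K$values - t(K$values))), 1e-10)
  expect_lt(max(abs(rowSums(K$values))), 1e-8)
  ev <- eigen(K$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("mean diagonal is near 1 for HWE genotypes centered at the true frequencies", {
  set.seed(33)
  p <- runif(1000, 0.1, 0.9)
  dos <- matrix(rbinom(200 * 1000, 2, rep(p, each = 200)), 200, 1000)
  K <- vanraden1(genotype_matrix(dos), p = p)
  expect_lt(abs(mean(diag(K$values)) - 1), 0.05)
})

test_that("block_kernel zeroes exactly the requested cross-group blocks", {
  dos <- unclass(tiny_genotypes())
  G <- genotype_matrix(dos)
  gs <- group_structure(c("A", "A", "B", "B", "C", "C"))
  K <- vanraden1(G, groups = gs)

  Kp <- block_kernel(K, "per-group")
  expect_equal(Kp$values[1:2, 3:6], matrix(0, 2, 4), ignore_attr = TRUE)
  expect_equal(Kp$values[1:2, 1:2], K$values[1:2, 1:2])

  Kh <- block_kernel(K, "hy-vs-rest", isolated_group = "C")
  expect_equal(Kh$values[1:4, 5:6], matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(Kh$values[1:4, 1:4], K$values[1:4, 1:4])  # A-B retained
  expect_equal(Kh$values[5:6, 5:6], K$values[5:6, 5:6])

  # idempotence
  expect_identical(block_kernel(Kp, "per-group")$values, Kp$values)

  expect_error(block_kernel(K, "hy-vs-rest"), "isolated_group")
  expect_error(block_kernel(K, "hy-vs-rest", isolated_group = "Z"), "unknown group")
})

test_that("per-group blocking equals the direct sum of within-group pieces", {
  set.seed(5)
  dat <- simulate_genotypes(sim_config(n_per_group = c(20, 15, 10), m = 150,
                                       seed = 5))
  G <- dat$genotypes; gs <- dat$groups
  p <- allele_frequency(G)
  K <- block_kernel(vanraden1(G, p, groups = gs), "per-group")
  Z <- centered_matrix(G, p)
  cc <- sum(2 * p$p * (1 - p$p))
  direct <- matrix(0, nrow(G), nrow(G))
  for (l in gs$labels) {
    i <- which(gs$assignment == l)
    direct[i, i] <- tcrossprod(Z[i, , drop = FALSE]) / cc
  }
  expect_equal(unname(K$values), direct, tolerance = 1e-12)
  ev <- eigen(K$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("gstar reduces to vanraden1 when groups share frequencies", {
  G <- tiny_genotypes()
  gs <- tiny_groups()
  p <- allele_frequency(G)
  Ks <- gstar(G, gs, per_group_freqs = list(p, p))
  Kv <- vanraden1(G, p)
  expect_equal(Ks$values, Kv$values, tolerance = 1e-12)
  expect_equal(unname(Ks$scaling_constant), rep(Kv$scaling_constant, 2))
})

test_that("gstar matches the hand-evaluated block formula on a one-SNP case", {
  # 2 groups x 2 animals, 1 informative SNP (plus a constant-het filler SNP
  # that contributes nothing); hand frequencies 0.5 and 0.1
  dos <- cbind(c(0L, 2L, 0L, 1L), c(1L, 1L, 1L, 1L))
  G <- genotype_matrix(dos)
  gs <- group_structure(c("A", "A", "B", "B"))
  p1 <- c(0.5, 0.5); p2 <- c(0.1, 0.5)
  c1 <- 2 * 0.5 * 0.5 + 2 * 0.5 * 0.5      # 1.0
  c2 <- 2 * 0.1 * 0.9 + 2 * 0.5 * 0.5      # 0.68
  Ks <- gstar(G, gs, per_group_freqs = list(p1, p2))
  z1 <- cbind(c(-1, 1), c(0, 0))           # group A centered at p1
  z2 <- cbind(c(-0.2, 0.8), c(0, 0))       # group B centered at p2
  expect_equal(Ks$values[1:2, 1:2], tcrossprod(z1) / c1, ignore_attr = TRUE)
  expect_equal(Ks$values[3:4, 3:4], tcrossprod(z2) / c2, ignore_attr = TRUE)
  expect_equal(Ks$values[1:2, 3:4], tcrossprod(z1, z2) / sqrt(c1 * c2),
               ignore_attr = TRUE)
  # product normalizer switch
  Kp <- gstar(G, gs, per_group_freqs = list(p1, p2), cross_norm = "product")
  expect_equal(Kp$values[1:2, 3:4], tcrossprod(z1, z2) / (c1 * c2),
               ignore_attr = TRUE)
  # PSD under the geometric normalizer
  ev <- eigen(Ks$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("kernel text export round-trips values and metadata", {
  G <- tiny_genotypes()
  K <- vanraden1(G, groups = tiny_groups())
  f <- tempfile()
  write_kernel(K, f)
  V <- as.matrix(read.delim(f, row.names = 1))
  expect_equal(unname(V), unname(K$values), tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$scheme, "common")
})
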