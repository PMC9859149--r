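test_that("matrix-text loader echoes dosages and validates input", {
  f <- write_geno_text(c("0 1", "2 1", "1 0"))
  G <- load_genotypes(f)
  expect_equal(unname(unclass(G)), rbind(c(0L, 1L), c(2L, 1L), c(1L, 0L)))

  f_bad <- write_geno_text(c("0 1", "3 1", "1 0"))
  expect_error(load_genotypes(f_bad), "row 2")

  f_empty <- write_geno_text(character())
  expect_error(load_genotypes(f_empty), "parse error")

  f_ragged <- write_geno_text(c("0 1", "2"))
  expect_error(load_genotypes(f_ragged), "line 2")

  f_junk <- write_geno_text(c("0 1", "x 1"))
  expect_error(load_genotypes(f_junk))
})

test_that("missing genotypes are rejected by default and mean-imputed on request", {
  f <- write_geno_text(c("0 1", "NA 1", "2 1", "2 1"))
  expect_error(load_genotypes(f), "missing")
  G <- suppressMessages(load_genotypes(f, missing = "mean"))
  # column mean of (0, 2, 2) = 4/3 -> rounds to 1
  expect_equal(unclass(G)[2, 1], 1L)
  expect_equal(attr(G, "n_imputed"), 1L)
})

test_that("write/read round trip reproduces dosages and ids exactly", {
  G <- tiny_genotypes()
  f <- tempfile()
  write_genotypes(G, f)
  G2 <- load_genotypes(f, snp_file = paste0(f, ".snps"),
                       animal_file = paste0(f, ".animals"))
  expect_identical(unclass(G2), unclass(G))
})

test_that("PLINK-style .raw files load", {
  f <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_G",
               "f1 a1 0 0 1 -9 0 2",
               "f2 a2 0 0 1 -9 1 1",
               "f3 a3 0 0 1 -9 2 0"), f)
  G <- suppressMessages(load_genotypes(f, format = "raw"))
  expect_equal(dim(G), c(3L, 2L))
  expect_equal(rownames(G), c("a1", "a2", "a3"))
  expect_equal(unname(unclass(G)[, 1]), c(0L, 1L, 2L))
})

test_that("allele frequencies are half the mean dosage", {
  G <- genotype_matrix(cbind(c(0, 1, 2), c(2, 2, 2)))
  p <- allele_frequency(G)
  expect_equal(unname(p$p), c(0.5, 1.0))
  expect_equal(p$scope, "all")

  G2 <- genotype_matrix(cbind(c(0, 0, 1, 1), c(1, 1, 1, 1)))
  expect_equal(unname(allele_frequency(G2)$p[1]), 0.25)  # 2/8 by hand

  expect_error(allele_frequency(G, subset = integer(0)), "empty")
})

test_that("frequency over a union is the size-weighted mean of subsets", {
  set.seed(4)
  G <- genotype_matrix(matrix(rbinom(200 * 20, 2, 0.3), 200, 20))
  s1 <- 1:70; s2 <- 71:200
  p_all <- allele_frequency(G)$p
  p1 <- allele_frequency(G, s1)$p
  p2 <- allele_frequency(G, s2)$p
  expect_equal(p_all, (70 * p1 + 130 * p2) / 200, tolerance = 1e-12)
})

test_that("qc_filter applies MAF and HWE rules with per-SNP reasons", {
  # col 1: monomorphic (p = 1) -> maf; col 2: genotype counts (15, 30, 15),
  # exact HWE at p = 0.5 -> kept; col 3: counts (30, 0, 30) -> chi2 = 60,
  # dropped by hwe
  dos <- cbind(rep(2L, 60),
               c(rep(0L, 15), rep(1L, 30), rep(2L, 15)),
               c(rep(0L, 30), rep(2L, 30)))
  G <- genotype_matrix(dos)
  qc <- qc_filter(G, maf_min = 0.01, hwe_alpha = 0.001)
  expect_equal(qc$report$reason, c("maf", NA, "hwe"))
  expect_equal(colnames(qc$genotypes), "snp2")
  # chi-square for counts (30, 0, 30) vs expected (15, 30, 15) is 60
  expect_equal(qc$report$hwe_p[3], pchisq(60, 1, lower.tail = FALSE))
  expect_equal(qc$report$hwe_p[2], 1)
})

test_that("qc_filter is idempotent", {
  set.seed(9)
  dat <- simulate_genotypes(sim_config(n_per_group = c(60, 40, 20), m = 300,
                                       seed = 9))
  once <- qc_filter(dat$genotypes)
  twice <- qc_filter(once$genotypes)
  expect_true(all(twice$report$kept))
  expect_identical(unclass(twice$genotypes), unclass(once$genotypes))
})

test_that("phenotype loader aligns animals with the genotypes", {
  G <- tiny_genotypes()
  f <- tempfile(fileext = ".csv")
  ph <- data.frame(animal_id = rev(rownames(G)), group = rep(c("B", "A"), each = 3),
                   year = "y1", age = 29:34, trait = rnorm(6))
  write.csv(ph, f, row.names = FALSE)
  out <- load_phenotypes(f, G)
  expect_equal(out$animal_id, rownames(G))
  expect_s3_class(out$group, "factor")
  expect_error(load_phenotypes(f, genotype_matrix(unclass(G)[1:4, ])),
               "do not match")
})

test_that("group_structure validates sizes and labels", {
  gs <- group_structure(c("x", "x", "y"), labels = c("x", "y"))
  expect_equal(gs$sizes, c(2L, 1L))
  expect_error(group_structure(c("x", "x"), labels = c("x", "y")), "empty group")
})
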