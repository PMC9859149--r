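# Synthetic group-structured genotypes and phenotypes.

#' Simulation settings
#'
#' Defaults emulate the statistical structure of a multi-subpopulation
#' beef-cattle carcass dataset at desk scale: three groups in proportions
#' 1036:733:279 scaled to about 500 animals, the smallest group more
#' diverged (higher Fst) than the two connected groups, ancestral
#' counted-allele frequencies uniform on (0.05, 0.95), 3000 SNPs, and
#' per-SNP effect variances set so the expected common and specific
#' genomic variances are 0.35 and 0.15 on a trait with residual variance
#' 0.5 (heritability 0.5, between-group genetic correlation 0.7). A
#' `full_scale = TRUE` preset restores the 1036/733/279 group sizes. Loci
#' are simulated independently (no linkage disequilibrium): group-specific
#' effects stand in for LD-phase differences between groups, which is the
#' structure the models fit.
#'
#' @param n_per_group integer vector of group sizes.
#' @param m number of SNPs.
#' @param group_labels group names; the first group is the reference group
#'   downstream; the last group plays the diverged, isolated role.
#' @param fst per-group Balding-Nichols divergence from the ancestral
#'   frequencies, in `[0, 1)`.
#' @param base_freq_range range of the ancestral counted-allele frequency.
#' @param var_u,var_d per-SNP variances of the common and group-specific
#'   effects; when `NULL` they are derived from `target_vg1` / `target_vg2`
#'   and the expected scaling constant `c = m * E[2p(1-p)]` of the
#'   ancestral frequency distribution (so `E[sigma_g1^2] = target_vg1`,
#'   `E[sigma_g2^2] = target_vg2`).
#' @param target_vg1,target_vg2 expected genomic variances used to derive
#'   `var_u` / `var_d` when those are `NULL`.
#' @param var_e residual phenotypic variance.
#' @param group_shift fixed effect of each group on the trait.
#' @param n_years number of year classes; year effects are drawn
#'   `N(0, sd_year^2)` once per dataset.
#' @param sd_year SD of the year effects.
#' @param age_range months; ages are uniform within it.
#' @param age_lin,age_quad linear and quadratic age coefficients (applied
#'   to age centered at the middle of `age_range`).
#' @param qtl optional indices of causal loci (QTL mode). Default `NULL`
#'   means every marker is causal (marker mode).
#' @param var_beta variance of the per-animal residual genetic part not
#'   captured by the markers (QTL mode; 0 disables it).
#' @param full_scale use the unscaled 1036/733/279 group sizes.
#' @param seed integer seed making the whole dataset reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(253L, 179L, 68L),
                       m = 3000L,
                       group_labels = c("A", "B", "C"),
                       fst = c(0.02, 0.02, 0.10),
                       base_freq_range = c(0.05, 0.95),
                       var_u = NULL, var_d = NULL,
                       target_vg1 = 0.35, target_vg2 = 0.15,
                       var_e = 0.5,
                       group_shift = c(0, 0.3, -0.8),
                       n_years = 5L, sd_year = 0.3,
                       age_range = c(28, 32),
                       age_lin = 0.05, age_quad = -0.01,
                       qtl = NULL, var_beta = 0,
                       full_scale = FALSE, seed = 1L) {
  if (full_scale) n_per_group <- c(1036L, 733L, 279L)
  ng <- length(n_per_group)
  stopifnot(all(n_per_group >= 2L), m >= 1L,
            length(group_labels) == ng, length(fst) == ng,
            all(fst >= 0), all(fst < 1),
            length(group_shift) == ng,
            var_e >= 0, var_beta >= 0, n_years >= 1L)
  # expected 2p(1-p) under U(a, b): 2*(E p - E p^2)
  a <- base_freq_range[1L]; b <- base_freq_range[2L]
  e2pq <- 2 * ((a + b) / 2 - (a^2 + a * b + b^2) / 3)
  c_expect <- m * e2pq
  if (is.null(var_u)) var_u <- target_vg1 / c_expect
  if (is.null(var_d)) var_d <- target_vg2 / c_expect
  stopifnot(var_u >= 0, var_d >= 0)
  structure(list(n_per_group = as.integer(n_per_group), m = as.integer(m),
                 group_labels = group_labels, fst = fst,
                 base_freq_range = base_freq_range,
                 var_u = var_u, var_d = var_d, var_e = var_e,
                 expected_c = c_expect,
                 group_shift = group_shift, n_years = as.integer(n_years),
                 sd_year = sd_year, age_range = age_range,
                 age_lin = age_lin, age_quad = age_quad,
                 qtl = qtl, var_beta = var_beta, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate group-structured SNP genotypes
#'
#' Ancestral counted-allele frequencies are drawn uniformly on
#' `base_freq_range`; each group's frequency at each SNP is drawn from the
#' Balding-Nichols model, `Beta(p (1-F)/F, (1-p)(1-F)/F)` with the group's
#' Fst `F` (equal to the ancestral frequency when `F = 0`); dosages are
#' `Binomial(2, group frequency)`, i.e. within-group Hardy-Weinberg
#' sampling. Returned group frequencies are the true (drawn) ones, not the
#' realized sample frequencies.
#'
#' @param cfg a [sim_config()].
#' @return A list: `genotypes` ([genotype_matrix()]), `groups`
#'   ([group_structure()]), `base_freq` (ancestral [allele_frequency()]),
#'   `group_freqs` (list of per-group true [allele_frequency()]).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m; ng <- length(cfg$n_per_group); n <- sum(cfg$n_per_group)
  p0 <- runif(m, cfg$base_freq_range[1L], cfg$base_freq_range[2L])
  pg <- vector("list", ng)
  for (k in seq_len(ng)) {
    F <- cfg$fst[k]
    pg[[k]] <- if (F > 0)
      rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    else p0
  }
  dos <- matrix(0L, n, m)
  row0 <- 0L
  for (k in seq_len(ng)) {
    nk <- cfg$n_per_group[k]
    dos[row0 + seq_len(nk), ] <- matrix(
      rbinom(nk * m, 2L, rep(pg[[k]], each = nk)), nk, m)
    row0 <- row0 + nk
  }
  groups <- group_structure(rep(cfg$group_labels, cfg$n_per_group),
                            labels = cfg$group_labels)
  G <- genotype_matrix(dos)
  list(genotypes = G, groups = groups,
       base_freq = structure(list(p = p0, scope = "all"),
                             class = "allele_freq"),
       group_freqs = lapply(seq_len(ng), function(k)
         structure(list(p = pg[[k]], scope = cfg$group_labels[k]),
                   class = "allele_freq")))
}

#' Simulate phenotypes under the common + group-specific marker model
#'
#' Common effects `u ~ N(0, var_u I)` and group-specific effects
#' `d_k ~ N(0, var_d I)` are drawn once; the genetic value of animal j in
#' group k is `sum_i z_ji (u_i + d_ki)` with `z` the dosage centered at
#' the pooled counted-allele frequencies. Phenotype = group shift + year
#' effect + linear and quadratic age terms + genetic value + `N(0, var_e)`.
#' In QTL mode (`cfg$qtl` set and/or `var_beta > 0`) only the causal loci
#' carry effects and an extra per-animal genetic residual `N(0, var_beta)`
#' represents the part not captured by the markers; with all markers causal
#' and `var_beta = 0` this collapses exactly to marker mode.
#'
#' The returned truth records both the expected variance components implied
#' by the generating parameters (`sigma_g1^2 = c var_u`,
#' `sigma_g2^2 = c var_d`, expected `r_g = var_u / (var_u + var_d)`) and
#' realized values recomputed from the sampled effects and genotypes.
#'
#' @param G a [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param groups the matching [group_structure()].
#' @param cfg the [sim_config()] (its `seed + 1` seeds the phenotype layer
#'   so genotypes and phenotypes are independently reproducible).
#' @return A list: `pheno` (data.frame: animal_id, group, year, age,
#'   trait), `truth` (class `sim_truth`).
#' @export
simulate_phenotypes <- function(G, groups, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(groups, "group_structure"),
            inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(G); m <- ncol(G); ng <- length(groups$labels)
  qtl <- cfg$qtl %||% seq_len(m)
  p <- allele_frequency(G)$p
  Z <- centered_matrix(G, p)

  u <- numeric(m); d <- matrix(0, m, ng)
  u[qtl] <- rnorm(length(qtl), 0, sqrt(cfg$var_u))
  for (k in seq_len(ng)) d[qtl, k] <- rnorm(length(qtl), 0, sqrt(cfg$var_d))

  g_common <- drop(Z %*% u)
  g_specific <- numeric(n)
  for (k in seq_len(ng)) {
    i <- groups$assignment == groups$labels[k]
    g_specific[i] <- Z[i, , drop = FALSE] %*% d[, k]
  }
  beta <- if (cfg$var_beta > 0) rnorm(n, 0, sqrt(cfg$var_beta)) else numeric(n)

  year <- factor(sample(paste0("y", seq_len(cfg$n_years)), n, replace = TRUE))
  year_eff <- setNames(rnorm(cfg$n_years, 0, cfg$sd_year),
                       paste0("y", seq_len(cfg$n_years)))
  age <- runif(n, cfg$age_range[1L], cfg$age_range[2L])
  age_c <- age - mean(cfg$age_range)
  shift <- cfg$group_shift[as.integer(groups$assignment)]

  eps <- rnorm(n, 0, sqrt(cfg$var_e))
  yv <- shift + year_eff[as.character(year)] + cfg$age_lin * age_c +
    cfg$age_quad * age_c^2 + g_common + g_specific + beta + eps

  cc <- sum(2 * p * (1 - p))
  realized_vg1 <- stats::var(g_common)
  realized_vg2 <- stats::var(g_specific)
  truth <- structure(list(
    u_true = u, d_true = d, qtl = qtl, beta = beta,
    g_common = g_common, g_specific = g_specific,
    year_effects = year_eff,
    c_pooled = cc,
    expected_vg1 = cc * cfg$var_u,
    expected_vg2 = cc * cfg$var_d,
    expected_rg = if (cfg$var_u + cfg$var_d > 0)
      cfg$var_u / (cfg$var_u + cfg$var_d) else NA_real_,
    realized_vg1 = realized_vg1,
    realized_vg2 = realized_vg2,
    realized_rg = if (realized_vg1 + realized_vg2 > 0)
      realized_vg1 / (realized_vg1 + realized_vg2) else NA_real_,
    realized_h2 = (realized_vg1 + realized_vg2) /
      (realized_vg1 + realized_vg2 + cfg$var_beta + cfg$var_e)
  ), class = "sim_truth")

  pheno <- data.frame(animal_id = rownames(G),
                      group = as.character(groups$assignment),
                      year = year, age = age, trait = as.numeric(yv),
                      stringsAsFactors = FALSE)
  list(pheno = pheno, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: expected vg1 = %.3g, vg2 = %.3g, rg = %.2f; ",
                     "realized vg1 = %.3g, vg2 = %.3g, rg = %.2f, h2 = %.2f\n"),
              x$expected_vg1, x$expected_vg2, x$expected_rg,
              x$realized_vg1, x$realized_vg2, x$realized_rg, x$realized_h2))
  invisible(x)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @return A list: `genotypes`, `groups`, `base_freq`, `group_freqs`,
#'   `pheno`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  gen <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gen$genotypes, gen$groups, cfg)
  c(gen, ph)
}
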