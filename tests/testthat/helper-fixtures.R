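# Small deterministic fixtures built in code.

# 6 animals x 4 SNPs, two groups, hand-written dosages
tiny_genotypes <- function() {
  dos <- rbind(c(0, 1, 2, 1),
               c(1, 1, 0, 2),
               c(2, 0, 1, 1),
               c(0, 2, 1, 0),
               c(1, 2, 2, 1),
               c(2, 1, 0, 0))
  genotype_matrix(dos, snp_ids = paste0("s", 1:4),
                  animal_ids = paste0("a", 1:6))
}

tiny_groups <- function() group_structure(c("A", "A", "A", "B", "B", "B"),
                                          labels = c("A", "B"))

# genotype matrix with prescribed genotype counts (n0, n1, n2) in one column
counts_column <- function(n0, n1, n2, extra_col = TRUE) {
  col <- c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
  dos <- if (extra_col) cbind(col, rep(c(0L, 1L), length.out = length(col)))
         else cbind(col)
  genotype_matrix(dos)
}

# write a matrix-text genotype file and return its path
write_geno_text <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# quick full fit on a small simulated dataset
fit_sim_model <- function(dat, model_id, chain, qc = TRUE) {
  G <- if (qc) qc_filter(dat$genotypes)$genotypes else dat$genotypes
  G1 <- vanraden1(G, groups = dat$groups)
  iso <- dat$groups$labels[length(dat$groups$labels)]
  kern <- switch(as.character(model_id),
    "1" = make_model(1, common = G1),
    "2" = make_model(2, common = G1,
                     specific = block_kernel(G1, "hy-vs-rest", iso)),
    "3" = make_model(3, specific = block_kernel(G1, "hy-vs-rest", iso)),
    "4" = make_model(4, common = G1, specific = block_kernel(G1, "per-group")),
    "5" = make_model(5, specific = block_kernel(G1, "per-group")))
  X <- build_design(dat$pheno, groups = dat$groups)
  run_chain(dat$pheno$trait, X, kern, chain = chain)
}
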