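# Back-solving SNP effects from kernel GBVs; GBV tables and reports.

#' Back-solve SNP allele substitution effects from breeding values
#'
#' Given posterior-mean breeding values `g_hat` for a kernel built from the
#' centered dosage matrix `Z`, the implied per-SNP effects are
#' `a_hat = Z' K^{-1} g_hat / c`. For a blocked kernel the system is
#' block-diagonal, so the solve is done per block using that block's
#' animals: one effect vector per group for a per-group kernel, and one for
#' the merged non-isolated groups plus one for the isolated group for a
#' hy-vs-rest kernel (the merged block is solved jointly, matching the
#' merged-group reporting of the specific effects). The inverse is the
#' eigen-truncated pseudo-inverse (eigenvalues below `tol` dropped), the
#' same representation the sampler uses: breeding values always lie in the
#' kernel's column space, where the pseudo-inverse solve is exact, and
#' near-singular blocked kernels need no ridge.
#'
#' @param Z centered dosage matrix (n x m), from [centered_matrix()] with
#'   the same frequencies used to build `K`.
#' @param K the `grm_kernel` the breeding values belong to.
#' @param g_hat breeding-value vector of length n (typically the posterior
#'   mean of the kernel's `g` component).
#' @param c scaling constant; defaults to the kernel's own.
#' @param tol eigenvalue truncation threshold for the pseudo-inverse
#'   (default `1e-8`).
#' @return An object of class `snp_effect_set`: an m x (number of blocks)
#'   matrix of effects in trait units per counted-allele copy, columns
#'   named `"common"` for a common kernel or by block (group or merged
#'   groups) otherwise.
#' @export
backsolve_snp_effects <- function(Z, K, g_hat, c = NULL, tol = 1e-8) {
  stopifnot(inherits(K, "grm_kernel"), nrow(Z) == length(g_hat),
            nrow(K$values) == length(g_hat))
  if (is.null(c)) c <- K$scaling_constant
  if (length(c) != 1L)
    stop("a single scaling constant is required (gstar kernels are not back-solved)")
  solve_block <- function(idx) {
    e <- eigen(K$values[idx, idx, drop = FALSE], symmetric = TRUE)
    keep <- e$values > tol
    if (!any(keep)) stop("kernel block has no eigenvalue above the truncation tolerance")
    U <- e$vectors[, keep, drop = FALSE]
    sol <- U %*% (crossprod(U, g_hat[idx]) / e$values[keep])
    drop(crossprod(Z[idx, , drop = FALSE], sol)) / c
  }
  if (K$scheme == "common") {
    eff <- matrix(solve_block(seq_along(g_hat)), ncol = 1L,
                  dimnames = list(colnames(Z), "common"))
  } else {
    blocks <- kernel_blocks(K)
    eff <- vapply(blocks, solve_block, numeric(ncol(Z)))
    dimnames(eff) <- list(colnames(Z), names(blocks))
  }
  structure(eff, class = c("snp_effect_set", "matrix", "array"))
}

#' @export
print.snp_effect_set <- function(x, ...) {
  cat(sprintf("snp_effect_set: %d SNPs x components [%s]\n", nrow(x),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

# Flatten a mixture of snp_effect_set objects / matrices / vectors into a
# named column matrix.
.effect_columns <- function(sets) {
  cols <- list()
  nm <- names(sets) %||% rep("", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (is.matrix(s)) {
      cn <- colnames(s) %||% paste0("c", seq_len(ncol(s)))
      pref <- if (nzchar(nm[i])) paste0(nm[i], ".") else ""
      for (j in seq_len(ncol(s))) cols[[paste0(pref, cn[j])]] <- s[, j]
    } else {
      cols[[if (nzchar(nm[i])) nm[i] else paste0("set", i)]] <- as.numeric(s)
    }
  }
  do.call(cbind, cols)
}

#' Correlation matrix of SNP effect sets
#'
#' Pearson or Spearman correlations between estimated effect vectors, the
#' standard cross-model comparison of allele substitution effects. A
#' zero-variance vector yields `NA` entries and a warning.
#'
#' @param sets list (optionally named) of effect vectors and/or
#'   [backsolve_snp_effects()] results; matrix columns are expanded with a
#'   `name.column` prefix.
#' @param method `"pearson"` or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
effect_correlation_table <- function(sets, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(unique(vapply(sets, NROW, numeric(1)))) > 1L)
    stop("effect sets have different lengths")
  M <- .effect_columns(sets)
  zv <- apply(M, 2L, stats::sd) == 0
  R <- suppressWarnings(stats::cor(M, method = method))
  if (any(zv)) {
    warning("zero-variance effect set(s): ",
            paste(colnames(M)[zv], collapse = ", "))
    R[zv, ] <- NA_real_; R[, zv] <- NA_real_
  }
  diag(R) <- 1
  R
}

#' Per-animal genomic breeding value table
#'
#' Posterior-mean breeding values per kernel component plus their sum (the
#' total GBV; for single-kernel models the total is the single component).
#'
#' @param fit a [run_chain()] result.
#' @param groups optional [group_structure()] to attach group labels.
#' @return A `data.frame`: `animal_id`, `group` (if given), one column per
#'   component (`g_common`, `g_specific`, ...), `gbv_total`.
#' @export
gbv_table <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "posterior_samples"))
  gm <- fit$posterior_means$g
  if (!length(gm)) stop("fit has no kernel components")
  out <- data.frame(animal_id = seq_along(fit$y))
  if (!is.null(rownames(fit$X))) out$animal_id <- rownames(fit$X)
  if (!is.null(groups)) out$group <- as.character(groups$assignment)
  tot <- 0
  for (nm in names(gm)) {
    out[[paste0("g_", nm)]] <- gm[[nm]]
    tot <- tot + gm[[nm]]
  }
  out$gbv_total <- tot
  out
}

#' Estimated group fixed effects from a fit
#'
#' Posterior means of the treatment-coded group coefficients, expressed per
#' group with the reference group at 0.
#'
#' @param fit a [run_chain()] result.
#' @param groups a [group_structure()] (its label order identifies the
#'   reference group).
#' @return Named numeric vector, one entry per group.
#' @export
group_effects <- function(fit, groups) {
  b <- fit$posterior_means$b
  out <- setNames(numeric(length(groups$labels)), groups$labels)
  for (l in groups$labels[-1L]) {
    cn <- paste0("group", l)
    if (cn %in% names(b)) out[l] <- b[[cn]]
  }
  out
}

#' Cross-model GBV report
#'
#' Compares per-animal total breeding values across models the way
#' multi-model evaluations are usually reported: (i) per-group Pearson and
#' Spearman correlations of each model's total GBVs with a reference
#' model's; (ii) per-group means of total GBVs expressed relative to a
#' reference group; (iii) the same means with each model's estimated group
#' fixed effect added, again relative to the reference group. The third
#' table exposes the confounding between group fixed effects and group
#' means of GBVs: shifts between a group's mean GBV across models are
#' largely absorbed by opposite shifts of the estimated group effect.
#'
#' @param tables named list of [gbv_table()] results (same animals, same
#'   order), one per model.
#' @param reference_model name (in `tables`) of the reference model for the
#'   correlations.
#' @param reference_group group label used as the zero point of the mean
#'   tables; default the first group present.
#' @param prefecture_effects optional named list, parallel to `tables`, of
#'   [group_effects()] vectors; required for the means-plus-effects table.
#' @return A list with `correlations`, `group_means`,
#'   `group_means_plus_effects` data.frames.
#' @export
gbv_report <- function(tables, reference_model = names(tables)[1L],
                       reference_group = NULL, prefecture_effects = NULL) {
  stopifnot(length(tables) >= 1L, reference_model %in% names(tables))
  ref <- tables[[reference_model]]
  if (is.null(ref$group)) stop("gbv tables need a 'group' column")
  for (tb in tables)
    if (!identical(tb$animal_id, ref$animal_id))
      stop("animal mismatch between gbv tables")
  grps <- unique(ref$group)
  if (is.null(reference_group)) reference_group <- grps[1L]

  safe_cor <- function(x, y, ...) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, ...)
  }
  cor_rows <- list()
  for (mn in names(tables)) {
    for (g in grps) {
      i <- ref$group == g
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        model = mn, group = g,
        pearson = safe_cor(tables[[mn]]$gbv_total[i], ref$gbv_total[i]),
        spearman = safe_cor(tables[[mn]]$gbv_total[i], ref$gbv_total[i],
                            method = "spearman"))
    }
  }
  correlations <- do.call(rbind, cor_rows)

  means <- vapply(tables, function(tb)
    vapply(grps, function(g) mean(tb$gbv_total[tb$group == g]), numeric(1)),
    numeric(length(grps)))
  means <- t(means)  # models x groups
  colnames(means) <- grps
  rel_means <- sweep(means, 1L, means[, reference_group])
  group_means <- data.frame(model = rownames(rel_means), rel_means,
                            row.names = NULL, check.names = FALSE)

  gmpe <- NULL
  if (!is.null(prefecture_effects)) {
    pe <- t(vapply(names(tables), function(mn)
      prefecture_effects[[mn]][grps], numeric(length(grps))))
    colnames(pe) <- grps
    tot <- means + pe
    tot <- sweep(tot, 1L, tot[, reference_group])
    gmpe <- data.frame(model = names(tables), tot,
                       row.names = NULL, check.names = FALSE)
  }
  list(correlations = correlations, group_means = group_means,
       group_means_plus_effects = gmpe)
}
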