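# VanRaden method-1 genomic relationship matrices and group-blocked variants.

new_grm_kernel <- function(values, scheme, scaling_constant, groups = NULL,
                           frequency_scope = "all", isolated_group = NULL) {
  structure(list(values = values,
                 scheme = scheme,
                 scaling_constant = scaling_constant,
                 groups = groups,
                 frequency_scope = frequency_scope,
                 isolated_group = isolated_group),
            class = "grm_kernel")
}

#' @export
print.grm_kernel <- function(x, ...) {
  cat(sprintf("grm_kernel (%s): %d x %d, c = %s\n", x$scheme,
              nrow(x$values), ncol(x$values),
              paste(signif(x$scaling_constant, 6), collapse = ", ")))
  invisible(x)
}

#' Allele-frequency-centered dosage matrix
#'
#' Entry (j, i) is `dosage(j, i) - 2 p_i`: the dosage of animal j at SNP i
#' centered at twice the counted-allele frequency. This is the `Z` matrix
#' of the marker model, the building block of every relationship matrix and
#' of the SNP-effect back-solve.
#'
#' @param G a [genotype_matrix()].
#' @param p an [allele_frequency()] object or numeric vector of length m.
#' @return A numeric n x m matrix.
#' @export
centered_matrix <- function(G, p) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (inherits(p, "allele_freq")) p <- p$p
  if (length(p) != ncol(G))
    stop(sprintf("dimension mismatch: %d frequencies for %d SNPs",
                 length(p), ncol(G)))
  sweep(unclass(G) + 0, 2L, 2 * p)
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = Z Z' / c` with `Z` the centered dosage matrix and
#' `c = sum_i 2 p_i (1 - p_i)`, so that the genomic variance is on the
#' scale of the base population implied by the frequencies used.
#'
#' @param G a [genotype_matrix()].
#' @param p frequencies used for centering and scaling; default: estimated
#'   from all animals in `G` (in which case rows/columns of the kernel sum
#'   to zero).
#' @param groups optional [group_structure()] attached to the kernel (needed
#'   by [block_kernel()]).
#' @return A `grm_kernel` with `scheme = "common"`.
#' @export
vanraden1 <- function(G, p = NULL, groups = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(p)) p <- allele_frequency(G)
  pv <- if (inherits(p, "allele_freq")) p$p else p
  cc <- sum(2 * pv * (1 - pv))
  if (cc <= 0) stop("scaling constant c = 0: all SNPs monomorphic at the supplied frequencies")
  Z <- centered_matrix(G, pv)
  K <- tcrossprod(Z) / cc
  K <- (K + t(K)) / 2
  new_grm_kernel(K, "common", cc, groups = groups)
}

# Index sets of the diagonal blocks a blocked kernel is a direct sum of.
kernel_blocks <- function(kernel) {
  gs <- kernel$groups
  switch(kernel$scheme,
    "per-group" = {
      out <- lapply(gs$labels, function(l) which(gs$assignment == l))
      names(out) <- gs$labels
      out
    },
    "hy-vs-rest" = {
      iso <- kernel$isolated_group
      rest <- setdiff(gs$labels, iso)
      out <- list(which(gs$assignment %in% rest),
                  which(gs$assignment == iso))
      names(out) <- c(paste(rest, collapse = "-"), iso)
      out
    },
    stop("kernel scheme '", kernel$scheme, "' has no block structure")
  )
}

#' Zero the cross-group blocks of a relationship matrix
#'
#' Produces the blocked kernels used to model group-specific marker
#' effects: `scheme = "per-group"` zeroes every cross-group block, leaving
#' a direct sum of within-group submatrices; `scheme = "hy-vs-rest"` zeroes
#' only the blocks linking one designated (isolated) group to the others,
#' so the remaining groups still share relationships. Both results are
#' direct sums of principal submatrices of the input and therefore remain
#' positive semidefinite.
#'
#' @param K a `grm_kernel` with `scheme = "common"` carrying a
#'   [group_structure()] (also accepts an already-blocked kernel, on which
#'   the operation is idempotent).
#' @param scheme `"per-group"` or `"hy-vs-rest"`.
#' @param isolated_group group label to cut off (required for
#'   `"hy-vs-rest"`).
#' @return A `grm_kernel` with the requested scheme; the scaling constant
#'   and frequencies are inherited from `K`.
#' @export
block_kernel <- function(K, scheme = c("per-group", "hy-vs-rest"),
                         isolated_group = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(K, "grm_kernel"))
  if (is.null(K$groups)) stop("kernel carries no group structure")
  gs <- K$groups
  if (scheme == "hy-vs-rest") {
    if (is.null(isolated_group))
      stop("isolated_group is required for scheme 'hy-vs-rest'")
    if (!isolated_group %in% gs$labels)
      stop("unknown group name: ", isolated_group)
  }
  V <- K$values
  g <- as.integer(gs$assignment)
  if (scheme == "per-group") {
    mask <- outer(g, g, "==")
  } else {
    iso <- g == match(isolated_group, gs$labels)
    mask <- !outer(iso, !iso, "&") & !outer(!iso, iso, "&")
  }
  V[!mask] <- 0
  new_grm_kernel(V, scheme, K$scaling_constant, groups = gs,
                 frequency_scope = K$frequency_scope,
                 isolated_group = if (scheme == "hy-vs-rest") isolated_group)
}

#' Multi-population relationship matrix with group-specific frequencies
#'
#' The construction often used for multi-breed genomic prediction: each
#' within-group block k is `Z_k Z_k' / c_k` with `Z_k` centered at that
#' group's own allele frequencies and `c_k = sum_i 2 p_ki (1 - p_ki)`;
#' cross-group blocks use each group's own centering and are divided by the
#' geometric mean `sqrt(c_j c_k)` (default) or by the product `c_j c_k`.
#' Under this kernel the between-group genetic correlation is fixed at 1
#' while the genomic variance may differ between groups.
#'
#' @param G a [genotype_matrix()].
#' @param groups a [group_structure()].
#' @param per_group_freqs optional list of [allele_frequency()] objects (or
#'   numeric vectors), one per group in `groups$labels` order; default:
#'   estimated within each group.
#' @param cross_norm `"geometric"` (default) or `"product"` normalizer for
#'   the cross-group blocks.
#' @return A `grm_kernel` with `scheme = "gstar"`; `scaling_constant` is the
#'   vector of per-group constants `c_k`.
#' @export
gstar <- function(G, groups, per_group_freqs = NULL,
                  cross_norm = c("geometric", "product")) {
  cross_norm <- match.arg(cross_norm)
  stopifnot(inherits(G, "genotype_matrix"), inherits(groups, "group_structure"))
  K <- length(groups$labels)
  idx <- lapply(groups$labels, function(l) which(groups$assignment == l))
  if (is.null(per_group_freqs))
    per_group_freqs <- lapply(seq_len(K), function(k)
      allele_frequency(G, subset = idx[[k]], scope = groups$labels[k]))
  pk <- lapply(per_group_freqs, function(p) if (inherits(p, "allele_freq")) p$p else p)
  ck <- vapply(pk, function(p) sum(2 * p * (1 - p)), numeric(1))
  if (any(ck <= 0))
    stop("scaling constant c = 0 in group ",
         paste(groups$labels[ck <= 0], collapse = ", "))
  Zk <- lapply(seq_len(K), function(k)
    centered_matrix(genotype_matrix(unclass(G)[idx[[k]], , drop = FALSE]), pk[[k]]))
  n <- nrow(G)
  V <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  for (j in seq_len(K)) for (k in j:K) {
    norm <- if (j == k) ck[j]
            else if (cross_norm == "geometric") sqrt(ck[j] * ck[k])
            else ck[j] * ck[k]
    B <- tcrossprod(Zk[[j]], Zk[[k]]) / norm
    V[idx[[j]], idx[[k]]] <- B
    if (j != k) V[idx[[k]], idx[[j]]] <- t(B)
  }
  V <- (V + t(V)) / 2
  out <- new_grm_kernel(V, "gstar", ck, groups = groups,
                        frequency_scope = "per-group")
  out$cross_norm <- cross_norm
  out
}

#' Heatmap of a relationship matrix
#'
#' Base-graphics image of the kernel with animals ordered by group, the
#' usual visual check that within-group blocks (especially of a more
#' inbred, diverged group) stand out.
#'
#' @param x a `grm_kernel`.
#' @param ... passed to [graphics::image()].
#' @export
plot.grm_kernel <- function(x, ...) {
  ord <- if (!is.null(x$groups)) order(x$groups$assignment) else seq_len(nrow(x$values))
  V <- x$values[ord, rev(ord)]
  graphics::image(seq_len(nrow(V)), seq_len(ncol(V)), V,
                  xlab = "animal", ylab = "animal",
                  main = sprintf("G (%s)", x$scheme),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Export a relationship matrix as plain text with a JSON sidecar
#'
#' @param K a `grm_kernel`.
#' @param path output file for the matrix (tab-separated); the scheme,
#'   group labels and scaling constants go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  stopifnot(inherits(K, "grm_kernel"))
  utils::write.table(K$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  meta <- list(scheme = K$scheme,
               scaling_constant = K$scaling_constant,
               frequency_scope = K$frequency_scope,
               isolated_group = K$isolated_group,
               groups = if (!is.null(K$groups))
                 list(labels = K$groups$labels,
                      assignment = as.character(K$groups$assignment)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
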