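# Genotype / phenotype / group I/O and SNP quality control.

#' Construct a genotype matrix object
#'
#' A `genotype_matrix` stores biallelic SNP dosages (0, 1, or 2 copies of the
#' counted allele) for `n` animals by `m` SNPs, together with unique animal
#' and SNP identifiers. The counted allele is fixed at load time and never
#' flipped downstream, so relationship matrices, back-solved effects and
#' simulated truths all refer to the same allele.
#'
#' @param dosages integer-valued matrix, animals in rows, SNPs in columns,
#'   entries in \{0, 1, 2\}, no missing values.
#' @param snp_ids,animal_ids optional identifier vectors; defaults are
#'   generated (`snp1..m`, `id1..n`).
#' @return An object of class `genotype_matrix`: the validated dosage matrix
#'   with `dimnames` set to the identifiers.
#' @export
genotype_matrix <- function(dosages, snp_ids = NULL, animal_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L || ncol(dosages) < 1L)
    stop("need at least 2 animals and 1 SNP")
  if (anyNA(dosages))
    stop("genotype matrix contains missing values")
  bad <- which(!(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(dosages))
    stop(sprintf("dosage %s outside {0,1,2} at row %d, column %d",
                 format(dosages[bad[1L]]), rc[1L], rc[2L]))
  }
  storage.mode(dosages) <- "integer"
  if (is.null(animal_ids)) animal_ids <- rownames(dosages)
  if (is.null(animal_ids)) animal_ids <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (length(animal_ids) != nrow(dosages) || length(snp_ids) != ncol(dosages))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(animal_ids)) stop("duplicated animal ids")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  dimnames(dosages) <- list(as.character(animal_ids), as.character(snp_ids))
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a genotype matrix from disk
#'
#' Two plain-text layouts are supported: `"matrix"` (whitespace-delimited
#' dosages, one animal per row, optional sidecar id files) and `"raw"`
#' (PLINK-style `.raw`: a header row, six leading columns
#' FID/IID/PAT/MAT/SEX/PHENOTYPE, then one dosage column per SNP).
#'
#' Missing genotypes (`NA`) are rejected by default; with
#' `missing = "mean"` each missing entry is replaced by the column mean
#' dosage rounded to the nearest of 0/1/2 and the imputed count is reported
#' via a message and the `"n_imputed"` attribute.
#'
#' @param path file to read.
#' @param format `"matrix"` or `"raw"`.
#' @param snp_file,animal_file optional sidecar files (one id per line) for
#'   the `"matrix"` format.
#' @param missing `"error"` (default) or `"mean"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("matrix", "raw"),
                           snp_file = NULL, animal_file = NULL,
                           missing = c("error", "mean")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("parse error: empty genotype file ", path)
    toks <- strsplit(trimws(lines), "[ \t]+")
    m <- length(toks[[1L]])
    dos <- matrix(NA_real_, length(toks), m)
    for (i in seq_along(toks)) {
      if (length(toks[[i]]) != m)
        stop(sprintf("parse error at line %d: expected %d fields, found %d",
                     i, m, length(toks[[i]])))
      v <- suppressWarnings(as.numeric(ifelse(toks[[i]] %in% c("NA", "-9"),
                                              NA, toks[[i]])))
      bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
      if (length(bad))
        stop(sprintf("validation error at row %d: dosage %s outside {0,1,2}",
                     i, toks[[i]][bad[1L]]))
      chk <- suppressWarnings(as.numeric(toks[[i]]))
      if (any(is.na(chk) & !(toks[[i]] %in% c("NA", "-9"))))
        stop(sprintf("parse error at line %d: non-numeric field", i))
      dos[i, ] <- v
    }
    animal_ids <- if (!is.null(animal_file)) readLines(animal_file) else NULL
    snp_ids <- if (!is.null(snp_file)) readLines(snp_file) else NULL
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                            na.strings = c("NA", "-9"))
    if (!nrow(dt) || ncol(dt) < 7L)
      stop("parse error: not a PLINK-style .raw file: ", path)
    animal_ids <- as.character(dt[["IID"]])
    dos <- as.matrix(dt[, -(1:6), drop = FALSE])
    snp_ids <- colnames(dos)
  }
  n_imp <- 0L
  if (anyNA(dos)) {
    if (missing == "error") {
      idx <- which(is.na(dos), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing genotype at row %d, column %d (use missing = \"mean\" to impute)",
                   idx[1L], idx[2L]))
    }
    for (j in which(colSums(is.na(dos)) > 0L)) {
      mu <- mean(dos[, j], na.rm = TRUE)
      if (is.nan(mu)) stop(sprintf("column %d entirely missing", j))
      nj <- sum(is.na(dos[, j]))
      dos[is.na(dos[, j]), j] <- min(2, max(0, round(mu)))
      n_imp <- n_imp + nj
    }
    message(sprintf("mean-imputed %d missing genotypes", n_imp))
  }
  out <- genotype_matrix(dos, snp_ids = snp_ids, animal_ids = animal_ids)
  if (n_imp > 0L) attr(out, "n_imputed") <- n_imp
  message(sprintf("loaded %d animals x %d SNPs from %s",
                  nrow(out), ncol(out), path))
  out
}

#' Write a genotype matrix as whitespace-delimited text
#'
#' Inverse of [load_genotypes()] with `format = "matrix"`; sidecar id files
#' are written next to `path` when requested, so a write/read round trip
#' reproduces the dosages and identifiers exactly.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @param ids write `<path>.animals` / `<path>.snps` sidecars (default TRUE).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, ids = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  writeLines(apply(unclass(G), 1L, paste, collapse = " "), path)
  if (ids) {
    writeLines(rownames(G), paste0(path, ".animals"))
    writeLines(colnames(G), paste0(path, ".snps"))
  }
  invisible(path)
}

#' Read a phenotype and covariate table
#'
#' Expects a CSV with at least the columns `animal_id`, `group`, `year`,
#' `age`, plus one column per trait. Every animal in `G` (when supplied)
#' must appear exactly once; rows are reordered to match the genotypes.
#'
#' @param path CSV file.
#' @param G optional [genotype_matrix()] used to check/align the rows.
#' @return A `data.frame` with `group` and `year` as factors.
#' @export
load_phenotypes <- function(path, G = NULL) {
  ph <- data.table::fread(path, data.table = FALSE)
  need <- c("animal_id", "group", "year", "age")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  ph$animal_id <- as.character(ph$animal_id)
  if (anyDuplicated(ph$animal_id)) stop("duplicated animal_id in phenotype table")
  if (!is.null(G)) {
    if (!setequal(ph$animal_id, rownames(G)))
      stop("phenotype animals do not match genotype animals")
    ph <- ph[match(rownames(G), ph$animal_id), , drop = FALSE]
    rownames(ph) <- NULL
  }
  ph$group <- factor(ph$group)
  ph$year <- factor(ph$year)
  trait_cols <- setdiff(names(ph), need)
  for (tc in trait_cols)
    if (is.numeric(ph[[tc]]) && any(!is.finite(ph[[tc]])))
      stop("non-finite phenotype in column ", tc)
  ph
}

#' Group structure of a population
#'
#' @param assignment factor or character vector of group labels, one per
#'   animal, in genotype row order.
#' @param labels optional ordering of the group labels (first label is the
#'   reference group downstream).
#' @return An object of class `group_structure` with fields `labels`,
#'   `assignment` (factor) and `sizes`.
#' @export
group_structure <- function(assignment, labels = NULL) {
  if (is.null(labels)) labels <- unique(as.character(assignment))
  assignment <- factor(as.character(assignment), levels = labels)
  if (anyNA(assignment)) stop("assignment contains labels not in 'labels'")
  sizes <- table(assignment)
  if (any(sizes == 0L)) stop("empty group: ",
                             paste(labels[sizes == 0L], collapse = ", "))
  structure(list(labels = labels,
                 assignment = assignment,
                 sizes = as.integer(sizes)),
            class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat("group_structure:",
      paste(sprintf("%s (n=%d)", x$labels, x$sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Counted-allele frequencies
#'
#' Frequency of the counted allele per SNP, `p_i = mean(dosage_i) / 2`,
#' computed over all animals or a subset (e.g. one group).
#'
#' @param G a [genotype_matrix()].
#' @param subset optional animal ids, indices, or logical vector.
#' @param scope label recorded on the result (`"all"` or a group name);
#'   defaults to `"all"` when no subset is given.
#' @return An object of class `allele_freq`: list with `p` (length-m vector
#'   in \[0,1\]) and `scope`.
#' @export
allele_frequency <- function(G, subset = NULL, scope = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  M <- unclass(G)
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, rownames(M))
    M <- M[subset, , drop = FALSE]
    if (!nrow(M)) stop("empty animal subset")
    if (is.null(scope)) scope <- "subset"
  } else if (is.null(scope)) scope <- "all"
  structure(list(p = colMeans(M) / 2, scope = scope), class = "allele_freq")
}

# 1-df chi-square goodness-of-fit test of Hardy-Weinberg proportions on the
# genotype counts of one SNP. Returns the p-value; monomorphic SNPs get 1
# (they carry no HWE information and are handled by the MAF filter).
hwe_pvalue <- function(dosage) {
  n <- length(dosage)
  n2 <- sum(dosage == 2L); n1 <- sum(dosage == 1L); n0 <- n - n1 - n2
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expc <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n0, n1, n2) - expc)^2 / expc)
  stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
}

#' SNP quality control: MAF and Hardy-Weinberg filters
#'
#' Keeps SNP i iff `min(p_i, 1 - p_i) > maf_min` and the 1-df chi-square
#' goodness-of-fit p-value of its genotype counts against Hardy-Weinberg
#' proportions exceeds `hwe_alpha`. Frequencies and HWE counts are computed
#' on the pooled matrix (all animals). The filter is idempotent. An exact
#' HWE test is a possible alternative for rare alleles; the closed-form
#' chi-square is used here.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minor-allele-frequency threshold (default 0.01, strict).
#' @param hwe_alpha HWE p-value threshold (default 0.001, strict).
#' @return An object of class `qc_result`: list with `genotypes` (filtered
#'   [genotype_matrix()]) and `report` (data.frame: snp_id, maf, hwe_p,
#'   kept, reason with `"maf"`/`"hwe"` for dropped SNPs).
#' @export
qc_filter <- function(G, maf_min = 0.01, hwe_alpha = 0.001) {
  stopifnot(inherits(G, "genotype_matrix"),
            maf_min >= 0, maf_min < 0.5, hwe_alpha > 0, hwe_alpha < 1)
  M <- unclass(G)
  p <- colMeans(M) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- apply(M, 2L, hwe_pvalue)
  keep_maf <- maf > maf_min
  keep_hwe <- hwe_p > hwe_alpha
  kept <- keep_maf & keep_hwe
  reason <- rep(NA_character_, length(p))
  reason[!keep_maf] <- "maf"
  reason[keep_maf & !keep_hwe] <- "hwe"
  report <- data.frame(snp_id = colnames(M), maf = maf, hwe_p = hwe_p,
                       kept = kept, reason = reason, row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(kept)) stop("all SNPs removed by QC")
  out <- genotype_matrix(M[, kept, drop = FALSE])
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result: kept %d / %d SNPs (dropped: %d maf, %d hwe)\n",
              sum(x$report$kept), nrow(x$report),
              sum(x$report$reason == "maf", na.rm = TRUE),
              sum(x$report$reason == "hwe", na.rm = TRUE)))
  invisible(x)
}
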