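# Fixed-effects design and the five kernel model variants.

#' Fixed-effects design matrix
#'
#' Builds the incidence matrix of the non-genetic part of the model:
#' intercept, treatment-coded group (first group as reference), treatment-
#' coded year class, and linear plus quadratic covariates of age centered
#' at its sample mean (centering reduces the collinearity between the two
#' age columns and leaves the intercept interpretable). Factors with a
#' single observed level carry no information and are dropped with a
#' warning.
#'
#' @param pheno data.frame with columns `group`, `year`, `age` (see
#'   [load_phenotypes()]).
#' @param groups optional [group_structure()]; when supplied its label
#'   order defines the reference group, otherwise factor levels are used.
#' @param nest_age if TRUE the age covariates are nested within group
#'   (separate linear and quadratic age regressions per group).
#' @return An object of class `fixed_design`: list with `X` (full-column-
#'   rank matrix, first column the intercept), `column_names`,
#'   `reference_levels` and `age_center`.
#' @export
build_design <- function(pheno, groups = NULL, nest_age = FALSE) {
  stopifnot(is.data.frame(pheno), nrow(pheno) >= 2L,
            all(c("group", "year", "age") %in% names(pheno)))
  grp <- if (!is.null(groups)) groups$assignment else factor(pheno$group)
  yr <- droplevels(factor(pheno$year))
  grp <- droplevels(grp)
  age_center <- mean(pheno$age)
  a <- pheno$age - age_center
  df <- data.frame(a = a, a2 = a^2)
  terms <- c("a", "a2")
  if (nlevels(grp) > 1L) {
    df$group <- grp
    terms <- c("group", terms)
  } else {
    warning("factor 'group' has a single level and was dropped")
  }
  if (nlevels(yr) > 1L) {
    df$year <- yr
    terms <- c(terms[terms == "group"], "year", terms[terms != "group"])
  } else {
    warning("factor 'year' has a single level and was dropped")
  }
  if (nest_age && nlevels(grp) > 1L)
    terms[terms %in% c("a", "a2")] <- c("group:a", "group:a2")
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = df)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  refs <- c(group = if (nlevels(grp) > 1L) levels(grp)[1L],
            year = if (nlevels(yr) > 1L) levels(yr)[1L])
  structure(list(X = X, column_names = colnames(X),
                 reference_levels = refs, age_center = age_center),
            class = "fixed_design")
}

#' @export
print.fixed_design <- function(x, ...) {
  cat(sprintf("fixed_design: %d x %d [%s]\n", nrow(x$X), ncol(x$X),
              paste(x$column_names, collapse = ", ")))
  invisible(x)
}

# role -> required kernel scheme, per model id
model_kernel_table <- list(
  `1` = c(common = "common"),
  `2` = c(common = "common", specific = "hy-vs-rest"),
  `3` = c(specific = "hy-vs-rest"),
  `4` = c(common = "common", specific = "per-group"),
  `5` = c(specific = "per-group")
)

#' Declare one of the five GBLUP model variants
#'
#' The variants differ only in which relationship kernels enter
#' `y = Xb + g_common + g_specific + e`:
#' model 1 fits a single common kernel (full G); model 2 adds a kernel in
#' which one isolated group shares no relationships with the rest
#' (common + hy-vs-rest); model 3 drops the common kernel from model 2;
#' model 4 pairs the common kernel with a fully group-blocked kernel
#' (common + per-group); model 5 drops the common kernel from model 4.
#' For models 2 and 4 the total genomic breeding value of an animal is the
#' sum of its common and specific components.
#'
#' @param model_id integer 1..5.
#' @param common,specific `grm_kernel` objects for the two roles; each
#'   model requires the schemes in the table above and rejects mismatches.
#' @return An object of class `model_config`: list with `model_id` and
#'   `kernels` (named list in role order).
#' @export
make_model <- function(model_id, common = NULL, specific = NULL) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("model_id must be in 1..5")
  need <- model_kernel_table[[as.character(model_id)]]
  supplied <- list(common = common, specific = specific)
  kernels <- list()
  for (role in names(need)) {
    k <- supplied[[role]]
    if (is.null(k))
      stop(sprintf("model %d requires a '%s' kernel", model_id, role))
    if (!inherits(k, "grm_kernel"))
      stop(sprintf("'%s' is not a grm_kernel", role))
    if (k$scheme != need[[role]])
      stop(sprintf("model %d requires scheme '%s' for role '%s', got '%s'",
                   model_id, need[[role]], role, k$scheme))
    kernels[[role]] <- k
  }
  extra <- names(supplied)[!vapply(supplied, is.null, logical(1))]
  extra <- setdiff(extra, names(need))
  if (length(extra))
    stop(sprintf("model %d does not take a '%s' kernel", model_id, extra[1L]))
  ns <- vapply(kernels, function(k) nrow(k$values), integer(1))
  if (length(unique(ns)) > 1L) stop("kernels have mismatching dimensions")
  structure(list(model_id = model_id, kernels = kernels),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model %d: %s\n", x$model_id,
              paste(sprintf("%s (%s)", names(x$kernels),
                            vapply(x$kernels, `[[`, "", "scheme")),
                    collapse = " + ")))
  invisible(x)
}
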