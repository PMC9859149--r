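# Posterior summaries: variance components, derived parameters, DIC table.

#' Phenotypic variance from variance components
#'
#' `sigma_p^2 = sigma_g1^2 + sigma_g2^2 + sigma_e^2`; components absent
#' from a model enter as zero.
#'
#' @param vg1 common genomic variance (0 when the model has no common
#'   kernel).
#' @param vg2 group-specific genomic variance (0 when absent).
#' @param ve residual variance.
#' @return The sum, in squared trait units.
#' @export
phenotypic_variance <- function(vg1 = 0, vg2 = 0, ve) {
  if (any(c(vg1, vg2, ve) < 0)) stop("variance components must be non-negative")
  vg1 + vg2 + ve
}

#' Genomic heritability
#'
#' `h^2 = (sigma_g1^2 + sigma_g2^2) / (sigma_g1^2 + sigma_g2^2 +
#' sigma_e^2)`: the fraction of phenotypic variance explained by the SNP
#' markers.
#'
#' @inheritParams phenotypic_variance
#' @return A value in \[0, 1\].
#' @export
heritability <- function(vg1 = 0, vg2 = 0, ve) {
  tot <- phenotypic_variance(vg1, vg2, ve)
  if (tot <= 0) stop("total variance must be positive")
  (vg1 + vg2) / tot
}

#' Between-group genetic correlation
#'
#' Under the common + group-specific partition of marker effects, the
#' correlation between the total marker effects of any two groups is
#' `r_g = sigma_g1^2 / (sigma_g1^2 + sigma_g2^2)`: only the common
#' component is shared, so the correlation is the common share of the
#' genomic variance. It is 1 when there are no group-specific effects and
#' 0 when there is no common component.
#'
#' @inheritParams phenotypic_variance
#' @return A value in \[0, 1\].
#' @export
genetic_correlation <- function(vg1, vg2) {
  if (any(c(vg1, vg2) < 0)) stop("variance components must be non-negative")
  den <- vg1 + vg2
  if (den <= 0) stop("sigma_g1^2 + sigma_g2^2 must be positive")
  vg1 / den
}

# role name -> reporting name used in the summary tables
.component_name <- function(role) {
  switch(role, common = "sigma_g1_sq", specific = "sigma_g2_sq",
         paste0("sigma_", role, "_sq"))
}

#' Summarize a fitted model
#'
#' Posterior means and SDs (reported as estimate and SE) of the variance
#' components, plus the derived parameters: phenotypic variance,
#' heritability and - when both a common and a specific kernel are present
#' - the between-group genetic correlation. Derived quantities are
#' computed per posterior draw and then averaged, the convention that
#' defines an SE for a ratio; for a nonlinear ratio this generally differs
#' from the ratio of posterior-mean components (the package reports the
#' per-draw convention, and [genetic_correlation()] etc. are available for
#' the ratio-of-means arithmetic). DIC is reported as a difference from a
#' baseline fit when one is given.
#'
#' @param fit a [run_chain()] result.
#' @param baseline optional baseline fit (or its [dic()]) for the
#'   delta-DIC column.
#' @param trait optional trait label carried into the table.
#' @return A `gblup_summary`: list with `model_id`, `trait`, `components`
#'   (data.frame of posterior mean and SD per parameter), `dic`,
#'   `delta_dic`.
#' @export
summarize_run <- function(fit, baseline = NULL, trait = NULL) {
  stopifnot(inherits(fit, "posterior_samples"))
  vd <- fit$var_draws
  roles <- names(fit$g_draws)
  comp <- data.frame(parameter = character(), mean = numeric(),
                     sd = numeric(), stringsAsFactors = FALSE)
  draws <- list()
  for (j in seq_along(roles))
    draws[[.component_name(roles[j])]] <- vd[, j]
  draws$sigma_e_sq <- vd[, ncol(vd)]

  vg1 <- if (!is.null(draws$sigma_g1_sq)) draws$sigma_g1_sq else 0
  vg2 <- if (!is.null(draws$sigma_g2_sq)) draws$sigma_g2_sq else 0
  draws$sigma_p_sq <- vg1 + vg2 + draws$sigma_e_sq
  draws$heritability <- (vg1 + vg2) / draws$sigma_p_sq
  if (!is.null(draws$sigma_g1_sq) && !is.null(draws$sigma_g2_sq))
    draws$genetic_correlation <- draws$sigma_g1_sq /
      (draws$sigma_g1_sq + draws$sigma_g2_sq)

  comp <- data.frame(
    parameter = names(draws),
    mean = vapply(draws, mean, numeric(1)),
    sd = vapply(draws, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  d <- dic(fit)
  delta <- NULL
  if (!is.null(baseline)) {
    db <- if (inherits(baseline, "dic")) baseline else dic(baseline)
    delta <- d$DIC - db$DIC
  }
  structure(list(model_id = fit$model_id, trait = trait,
                 components = comp, dic = d, delta_dic = delta,
                 convention = "derived parameters are per-draw means"),
            class = "gblup_summary")
}

#' @export
print.gblup_summary <- function(x, digits = 4, ...) {
  hdr <- sprintf("model %s%s", x$model_id %||% "?",
                 if (!is.null(x$trait)) paste0(" (", x$trait, ")") else "")
  cat(hdr, "\n")
  if (!is.null(x$delta_dic)) cat(sprintf("  delta DIC = %.1f\n", x$delta_dic))
  cat(sprintf("  DIC = %.1f (pD = %.1f)\n", x$dic$DIC, x$dic$pD))
  tab <- x$components
  tab$mean <- signif(tab$mean, digits); tab$sd <- signif(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model comparison table
#'
#' Collates [summarize_run()] results into one table: one row per model
#' with delta-DIC (relative to the designated baseline model, default the
#' first) and the posterior mean and SD of every variance component and
#' derived parameter.
#'
#' @param summaries named list of `gblup_summary` objects.
#' @return A `data.frame`, one row per model.
#' @export
model_comparison <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  base_dic <- summaries[[1L]]$dic$DIC
  rows <- lapply(summaries, function(s) {
    out <- data.frame(model = s$model_id %||% NA_integer_,
                      delta_DIC = s$dic$DIC - base_dic)
    for (i in seq_len(nrow(s$components))) {
      out[[s$components$parameter[i]]] <- s$components$mean[i]
      out[[paste0(s$components$parameter[i], "_se")]] <- s$components$sd[i]
    }
    out
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA_real_
    r[cols]
  })
  do.call(rbind, rows)
}
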