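# End-to-end orchestration: simulate/load -> QC -> kernels -> fits ->
# summaries -> effect and GBV reports, with a JSON run manifest.

default_pipeline_config <- function() {
  list(seed = 1L,
       out_dir = NULL,
       sim = list(),          # sim_config() arguments; NULL disables simulation
       genotypes = NULL,      # path (used when sim is NULL)
       phenotypes = NULL,
       trait = "trait",
       qc = list(maf_min = 0.01, hwe_alpha = 0.001),
       models = 1:5,
       isolated_group = NULL, # default: last group label
       chain = list(n_iter = 20000L, burn_in = 2000L, thin = 10L),
       priors = list(df = 5, R2 = 0.5),
       baseline_model = 1L)
}

validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("invalid config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (!all(cfg$models %in% 1:5)) stop("invalid config: models must be in 1..5")
  if (!is.null(cfg$chain$burn_in) && !is.null(cfg$chain$n_iter) &&
      cfg$chain$burn_in >= cfg$chain$n_iter)
    stop("invalid config: burn_in must be smaller than n_iter")
  if (is.null(cfg$sim) && (is.null(cfg$genotypes) || is.null(cfg$phenotypes)))
    stop("invalid config: either sim or genotypes+phenotypes paths required")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), SNP quality control,
#' construction of the common and blocked relationship kernels, Gibbs
#' sampling for each requested model variant, the model-comparison summary,
#' SNP-effect back-solving with cross-model effect correlations, and the
#' cross-model GBV report. Numeric reports are written as CSV under
#' `out_dir` together with a JSON manifest (config, seed, stage timings,
#' output files, package version). A stage failure stops the run but the
#' manifest records completed stages and the failed one.
#'
#' All chains derive their seeds deterministically from `config$seed`, so a
#' rerun with the same config reproduces every number bit for bit.
#'
#' @param config nested list (see `mkgblup:::default_pipeline_config()` for
#'   the keys) or path to an equivalent YAML file.
#' @return A list with `manifest` and the in-memory `results` (data,
#'   kernels, fits, summaries, reports), invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mkgblup")),
                   seed = cfg$seed, config = cfg, stages = list(),
                   outputs = character())
  results <- list()
  t_all <- proc.time()[["elapsed"]]

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }
  emit <- function(df, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, path)
  }

  # --- data ---------------------------------------------------------
  dat <- run_stage("data", {
    if (!is.null(cfg$sim)) {
      scfg <- do.call(sim_config, utils::modifyList(cfg$sim,
                                                    list(seed = cfg$seed)))
      simulate_dataset(scfg)
    } else {
      G <- load_genotypes(cfg$genotypes)
      ph <- load_phenotypes(cfg$phenotypes, G)
      list(genotypes = G, groups = group_structure(ph$group),
           pheno = ph)
    }
  })
  results$data <- dat

  # --- QC -----------------------------------------------------------
  qc <- run_stage("qc", qc_filter(dat$genotypes,
                                  maf_min = cfg$qc$maf_min,
                                  hwe_alpha = cfg$qc$hwe_alpha))
  emit(qc$report, "qc_report.csv")
  results$qc <- qc
  G <- qc$genotypes
  groups <- dat$groups
  iso <- cfg$isolated_group %||% groups$labels[length(groups$labels)]

  # --- kernels ------------------------------------------------------
  kernels <- run_stage("grm", {
    p <- allele_frequency(G)
    G1 <- vanraden1(G, p, groups = groups)
    list(G1 = G1,
         G2 = block_kernel(G1, "hy-vs-rest", isolated_group = iso),
         G3 = block_kernel(G1, "per-group"),
         Z = centered_matrix(G, p))
  })
  results$kernels <- kernels

  # --- fits ---------------------------------------------------------
  y <- dat$pheno[[cfg$trait]]
  design <- run_stage("design", build_design(dat$pheno, groups = groups))
  priors <- do.call(prior_spec, cfg$priors)
  model_kernels <- list(
    `1` = function() make_model(1, common = kernels$G1),
    `2` = function() make_model(2, common = kernels$G1, specific = kernels$G2),
    `3` = function() make_model(3, specific = kernels$G2),
    `4` = function() make_model(4, common = kernels$G1, specific = kernels$G3),
    `5` = function() make_model(5, specific = kernels$G3))
  fits <- run_stage("fit", {
    out <- list()
    for (mid in cfg$models) {
      ch <- do.call(chain_config,
                    utils::modifyList(cfg$chain,
                                      list(seed = cfg$seed + 100L + mid)))
      out[[paste0("model", mid)]] <-
        run_chain(y, design, model_kernels[[as.character(mid)]](),
                  priors = priors, chain = ch)
    }
    out
  })
  results$fits <- fits

  # --- summaries ----------------------------------------------------
  summaries <- run_stage("summarize", {
    base_name <- paste0("model", cfg$baseline_model)
    base <- if (base_name %in% names(fits)) dic(fits[[base_name]])
    lapply(fits, summarize_run, baseline = base, trait = cfg$trait)
  })
  emit(model_comparison(summaries), "variance_components.csv")
  results$summaries <- summaries

  # --- SNP effects --------------------------------------------------
  effects <- run_stage("effects", {
    sets <- list()
    for (mn in names(fits)) {
      fit <- fits[[mn]]
      for (role in names(fit$g_draws)) {
        kern <- switch(role,
                       common = kernels$G1,
                       specific = if (fit$model_id %in% c(2L, 3L)) kernels$G2
                                  else kernels$G3)
        eff <- backsolve_snp_effects(kernels$Z, kern,
                                     fit$posterior_means$g[[role]])
        for (cn in colnames(eff))
          sets[[paste0(mn, ".", if (cn == "common") "C" else cn)]] <- eff[, cn]
      }
    }
    sets
  })
  eff_cor <- effect_correlation_table(effects)
  emit(data.frame(effect = rownames(eff_cor), round(eff_cor, 3),
                  check.names = FALSE), "snp_effect_correlations.csv")
  results$snp_effects <- effects
  results$snp_effect_correlations <- eff_cor

  # --- GBV report ---------------------------------------------------
  gbv <- run_stage("gbv", {
    tables <- lapply(fits, gbv_table, groups = groups)
    pe <- lapply(fits, group_effects, groups = groups)
    gbv_report(tables, reference_model = names(fits)[1L],
               reference_group = groups$labels[1L],
               prefecture_effects = pe)
  })
  emit(gbv$correlations, "gbv_correlations.csv")
  emit(gbv$group_means, "gbv_group_means.csv")
  emit(gbv$group_means_plus_effects, "gbv_group_means_plus_effects.csv")
  results$gbv <- gbv

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  write_manifest(manifest, out_dir)
  invisible(list(manifest = manifest, results = results))
}

write_manifest <- function(manifest, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA, force = TRUE)
  file.rename(tmp, path)  # atomic on one filesystem
  invisible(path)
}
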