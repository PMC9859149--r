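# Gibbs sampler front end for y = Xb + sum_k g_k + e and the DIC.

#' MCMC chain settings
#'
#' Defaults follow the single-chain protocol used throughout the package's
#' reference analyses: 110,000 total samples, the first 10,000 discarded as
#' burn-in, thinning rate 10, giving 10,000 kept draws.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded (must be `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed optional integer seed; when set the chain is
#'   bit-reproducible.
#' @return A `chain_config` list.
#' @export
chain_config <- function(n_iter = 110000L, burn_in = 10000L, thin = 10L,
                         seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed), class = "chain_config")
}

#' Variance-component priors
#'
#' Every variance gets a scaled-inverse-chi-square prior. By default the
#' hyperparameters follow the rule used by standard Bayesian whole-genome
#' regression software: degrees of freedom `df = 5`, and scale chosen so
#' the prior mode of each genetic variance equals `var(y) * R2 / K` (K the
#' number of kernels) and the prior mode of the residual variance equals
#' `var(y) * (1 - R2)`, with `R2 = 0.5`. Since the mode of a
#' scaled-inv-chi-square(df, S) is `df S / (df + 2)`, the scales are
#' `mode * (df + 2) / df`. Fixed effects always get an improper flat prior.
#'
#' @param df prior degrees of freedom (> 0), shared by all variances.
#' @param R2 prior proportion of variance attributed to the kernels.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(df = 5, R2 = 0.5) {
  stopifnot(df > 0, R2 > 0, R2 < 1)
  structure(list(df = df, R2 = R2), class = "prior_spec")
}

# Eigendecomposition of a kernel, exploiting block-diagonal structure of
# the blocked schemes. Eigenvalues <= tol are truncated; returns U (n x r)
# and d (length r), so K ~= U diag(d) U' on the retained space.
eigen_kernel <- function(kernel, tol = 1e-8) {
  V <- kernel$values
  n <- nrow(V)
  if (kernel$scheme %in% c("per-group", "hy-vs-rest")) {
    blocks <- kernel_blocks(kernel)
    Us <- list(); ds <- list()
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      e <- eigen(V[idx, idx, drop = FALSE], symmetric = TRUE)
      keep <- e$values > tol
      U <- matrix(0, n, sum(keep))
      U[idx, ] <- e$vectors[, keep, drop = FALSE]
      Us[[b]] <- U; ds[[b]] <- e$values[keep]
    }
    U <- do.call(cbind, Us); d <- unlist(ds)
  } else {
    e <- eigen(V, symmetric = TRUE)
    keep <- e$values > tol
    U <- e$vectors[, keep, drop = FALSE]
    d <- e$values[keep]
  }
  if (!length(d)) stop("kernel has no eigenvalue above the truncation tolerance")
  list(U = U, d = d)
}

#' Run the Gibbs sampler for a multi-kernel GBLUP model
#'
#' Samples from the posterior of `y = Xb + sum_k g_k + e` with
#' `g_k ~ N(0, K_k sigma_k^2)` and `e ~ N(0, I sigma_e^2)`. Each kernel is
#' eigendecomposed (`K_k = U_k D_k U_k'`, eigenvalues below `tol`
#' truncated) and `g_k` is sampled through its coordinates in that basis,
#' which are conditionally independent given the rest; fixed effects are
#' drawn jointly from their multivariate-normal full conditional and the
#' variances from their scaled-inverse-chi-square full conditionals. The
#' conditional deviance `-2 log N(y | Xb + sum_k g_k, I sigma_e^2)` is
#' recorded at every kept draw for DIC computation.
#'
#' @param y numeric response vector (one record per animal).
#' @param X a [build_design()] result or numeric design matrix.
#' @param kernels a [make_model()] result, or a named list of `grm_kernel`
#'   objects (names become the `g` component names), or an empty list for a
#'   fixed-effects-only model.
#' @param priors a [prior_spec()].
#' @param chain a [chain_config()].
#' @param tol eigenvalue truncation threshold (default `1e-8`).
#' @return An object of class `posterior_samples`: kept draws of the fixed
#'   effects (`b_draws`, S x f), of each kernel's breeding values
#'   (`g_draws`, list of S x n matrices), of the variances (`var_draws`,
#'   S x (K+1), genetic components then residual) and of the deviance
#'   (`deviance_draws`), plus posterior means, the model/chain metadata and
#'   the data needed to evaluate the deviance at the posterior means.
#' @export
run_chain <- function(y, X, kernels = list(), priors = prior_spec(),
                      chain = chain_config(), tol = 1e-8) {
  t0 <- proc.time()[["elapsed"]]
  design <- if (inherits(X, "fixed_design")) X else NULL
  Xm <- if (is.null(design)) as.matrix(X) else design$X
  model <- NULL
  if (inherits(kernels, "model_config")) {
    model <- kernels
    kernels <- model$kernels
  }
  n <- length(y)
  stopifnot(is.numeric(y), all(is.finite(y)), nrow(Xm) == n)
  for (k in kernels) {
    stopifnot(inherits(k, "grm_kernel"))
    if (nrow(k$values) != n) stop("kernel dimension does not match length(y)")
    if (max(abs(k$values - t(k$values))) > 1e-8) stop("kernel is not symmetric")
  }
  K <- length(kernels)
  if (K > 0 && is.null(names(kernels)))
    names(kernels) <- paste0("g", seq_len(K))

  vy <- stats::var(y)
  df0 <- rep(priors$df, K + 1L)
  S0 <- c(if (K > 0) rep(vy * priors$R2 / K * (priors$df + 2) / priors$df, K),
          vy * (1 - priors$R2) * (priors$df + 2) / priors$df)

  eig <- lapply(kernels, eigen_kernel, tol = tol)
  kern_in <- lapply(eig, function(e)
    list(d = e$d, Uty = drop(crossprod(e$U, y)), UtX = crossprod(e$U, Xm)))
  cross <- lapply(seq_len(max(K, 1L)), function(k) {
    if (k < 2L) return(list())
    lapply(seq_len(k - 1L), function(l) crossprod(eig[[l]]$U, eig[[k]]$U))
  })[seq_len(K)]
  if (K == 0L) cross <- list()

  if (!is.null(chain$seed)) set.seed(chain$seed)
  raw <- .gibbs_gblup_cpp(n, crossprod(Xm), drop(crossprod(Xm, y)), sum(y^2),
                          kern_in, cross, df0, S0,
                          chain$n_iter, chain$burn_in, chain$thin)

  S <- nrow(raw$b_draws)
  colnames(raw$b_draws) <- colnames(Xm)
  g_draws <- vector("list", K); names(g_draws) <- names(kernels)
  for (k in seq_len(K))
    g_draws[[k]] <- raw$a_draws[[k]] %*% t(eig[[k]]$U)
  vn <- c(if (K > 0) paste0("sigma_", names(kernels), "_sq"), "sigma_e_sq")
  colnames(raw$var_draws) <- vn

  g_mean <- lapply(g_draws, colMeans)
  fit <- structure(list(
    b_draws = raw$b_draws,
    g_draws = g_draws,
    var_draws = raw$var_draws,
    deviance_draws = drop(raw$deviance_draws),
    posterior_means = list(b = colMeans(raw$b_draws), g = g_mean,
                           var = colMeans(raw$var_draws)),
    y = y, X = Xm,
    model_id = if (!is.null(model)) model$model_id,
    kernel_schemes = vapply(kernels, `[[`, "", "scheme"),
    ranks = vapply(eig, function(e) length(e$d), integer(1)),
    priors = priors, chain = chain,
    runtime = proc.time()[["elapsed"]] - t0
  ), class = "posterior_samples")
  fit
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d kept draws, %d fixed effects, %d kernel(s)%s\n",
              length(x$deviance_draws), ncol(x$b_draws), length(x$g_draws),
              if (!is.null(x$model_id)) sprintf(" [model %d]", x$model_id) else ""))
  pm <- x$posterior_means$var
  cat("posterior means:",
      paste(sprintf("%s = %.4g", names(pm), pm), collapse = ", "), "\n")
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the conditional
#' deviance `-2 log N(y | Xb + sum_k g_k, I sigma_e^2)` and
#' `pD = Dbar - Dhat`, where `Dhat` is the deviance evaluated at the
#' posterior means of `b`, the `g_k` and `sigma_e^2`. This is the
#' conditional-deviance convention of standard whole-genome regression
#' software; lower DIC indicates a better fit-complexity trade-off.
#'
#' @param object a `posterior_samples` fit, or (default method) a numeric
#'   vector of deviance draws.
#' @param ... unused.
#' @return A `dic` object: list with `DIC`, `pD`, `mean_deviance` and
#'   `deviance_at_means`.
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @rdname dic
#' @param deviance_at_means deviance evaluated at the posterior means
#'   (required by the default method).
#' @export
dic.default <- function(object, deviance_at_means, ...) {
  dev <- as.numeric(object)
  if (length(dev) < 2L) stop("need at least 2 kept draws")
  dbar <- mean(dev)
  pd <- dbar - deviance_at_means
  structure(list(DIC = dbar + pd, pD = pd, mean_deviance = dbar,
                 deviance_at_means = deviance_at_means), class = "dic")
}

#' @rdname dic
#' @export
dic.posterior_samples <- function(object, ...) {
  pm <- object$posterior_means
  mu <- drop(object$X %*% pm$b)
  for (g in pm$g) mu <- mu + g
  se2 <- pm$var[["sigma_e_sq"]]
  dhat <- length(object$y) * log(2 * pi * se2) + sum((object$y - mu)^2) / se2
  dic.default(object$deviance_draws, dhat)
}

#' @export
print.dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              x$DIC, x$mean_deviance, x$pD))
  invisible(x)
}

# Chain diagnostics logged rather than gated on: lag-1 autocorrelation and
# the corresponding AR(1) effective sample size for each variance draw.
chain_diagnostics <- function(fit) {
  vd <- fit$var_draws
  S <- nrow(vd)
  out <- data.frame(parameter = colnames(vd), lag1 = NA_real_, ess = NA_real_)
  for (j in seq_len(ncol(vd))) {
    x <- vd[, j]
    r1 <- stats::cor(x[-1L], x[-S])
    out$lag1[j] <- r1
    out$ess[j] <- S * (1 - r1) / (1 + r1)
  }
  out
}
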