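# Independent oracles used to compute expected values.

# Brute-force grid posterior for the single-kernel model
#   y = Xb + g + e, g ~ N(0, K vg), e ~ N(0, I ve), flat prior on b,
# scaled-inv-chi-square priors (df, Sg) on vg and (df, Se) on ve.
# b and g are marginalized analytically: y ~ N(Xb, K vg + I ve), so with a
# flat prior on b the marginal density at (vg, ve) is
#   |V|^{-1/2} |X'V^{-1}X|^{-1/2} exp(-r'V^{-1}r / 2),  r = y - X bhat(V).
# Everything is evaluated in the eigenbasis of K, where V is diagonal.
# Returns the normalized joint weights on a log-spaced grid plus the two
# marginal CDFs.
grid_posterior_1k <- function(y, X, K, df0, Sg, Se,
                              vg_range, ve_range, n_grid = 200) {
  e <- eigen(K, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)
  d <- pmax(e$values, 0)
  vg_grid <- exp(seq(log(vg_range[1]), log(vg_range[2]), length.out = n_grid))
  ve_grid <- exp(seq(log(ve_range[1]), log(ve_range[2]), length.out = n_grid))
  lp_prior <- function(x, df, S) -(df / 2 + 1) * log(x) - df * S / (2 * x)
  lp <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    w <- 1 / (vg_grid[i] * d + ve_grid[j])
    XtWX <- crossprod(Xt, w * Xt)
    XtWy <- drop(crossprod(Xt, w * yt))
    bhat <- solve(XtWX, XtWy)
    quad <- sum(w * yt^2) - sum(XtWy * bhat)
    ll <- -0.5 * (sum(log(vg_grid[i] * d + ve_grid[j])) +
                    determinant(XtWX, logarithm = TRUE)$modulus + quad)
    lp[i, j] <- ll + lp_prior(vg_grid[i], df0, Sg) +
      lp_prior(ve_grid[j], df0, Se)
  }
  # weights on a log grid must include the cell widths
  wg <- diff(c(vg_grid[1]^2 / vg_grid[2], vg_grid))  # ~ proportional widths
  we <- diff(c(ve_grid[1]^2 / ve_grid[2], ve_grid))
  lw <- lp + log(wg) + rep(log(we), each = n_grid)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(vg = vg_grid, ve = ve_grid, w = w,
       cdf_vg = cumsum(rowSums(w)), cdf_ve = cumsum(colSums(w)),
       edge_mass = sum(w[c(1, n_grid), ]) + sum(w[, c(1, n_grid)]))
}

# Kolmogorov-Smirnov distance between a grid CDF and an empirical sample
ks_grid_vs_sample <- function(grid_x, grid_cdf, draws) {
  emp <- vapply(grid_x, function(x) mean(draws <= x), numeric(1))
  max(abs(emp - grid_cdf))
}

# Fst estimator for a group relative to known ancestral frequencies:
# under the Balding-Nichols model E[(p_k - p)^2] = F p (1 - p).
fst_from_truth <- function(p_group, p_base) {
  mean((p_group - p_base)^2 / (p_base * (1 - p_base)))
}

# batch-means Monte Carlo standard error of a chain's mean
mcse <- function(x, n_batch = 50) {
  bs <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}
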