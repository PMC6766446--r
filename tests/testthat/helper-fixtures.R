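# Shared fixtures for the suite. All cohorts are generated in code; the
# reference site (BRF) must be present whenever preprocessing is exercised,
# since the dual-sugar reference model is fitted on it.

quick_mcmc <- function(seed = 1, n_chains = 2, n_iter = 1200,
                       n_burnin = 600) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
              seed = seed)
}

# low within-child measurement noise: used by the simulation studies that
# check sampler calibration on the latent scale (coverage, mediation), so
# that per-child means identify the latent standardized variables
low_noise <- function() {
  list(diet_recall = 0.1, fecal_month = 0.25, lm_test = 0.2)
}

# a single-arc truth: zinc density -> LMZ
zinc_lmz_truth <- function(beta = -0.14) {
  truth_dag(data.frame(parent = "zinc", child = "lmz", beta = beta))
}

# minimal mediation graph: zinc -> lmz -> low_retinol (optional direct arc)
mediation_spec <- function(direct = TRUE) {
  nodes <- data.frame(name = c("zinc", "lmz", "low_retinol"),
                      family = c("linear", "linear", "logistic"),
                      role = c("diet", "mediator", "outcome"))
  arcs <- data.frame(parent = c("zinc", "lmz"),
                     child = c("lmz", "low_retinol"))
  if (direct) {
    arcs <- rbind(arcs, data.frame(parent = "zinc", child = "low_retinol"))
  }
  network_spec(nodes, arcs)
}

# synthetic analytic-like data for direct network fits (already standardized)
linear_chain_data <- function(n = 600, b_xm = 0.5, b_my = 0.4, b_xy = 0.3,
                              seed = 1) {
  set.seed(seed)
  site <- sample(c("A", "B"), n, replace = TRUE)
  x <- rnorm(n)
  m <- b_xm * x + rnorm(n, 0, sqrt(max(0.05, 1 - b_xm^2)))
  y <- b_xy * x + b_my * m + rnorm(n, 0, 0.8)
  data.frame(site = site, x = x, m = m, y = y)
}

chain_spec <- function() {
  nodes <- data.frame(name = c("x", "m", "y"),
                      family = "linear",
                      role = c("diet", "mediator", "outcome"))
  arcs <- data.frame(parent = c("x", "x", "m"), child = c("m", "y", "y"))
  network_spec(nodes, arcs)
}

# conjugate normal-inverse-gamma posterior (flat-ish limit) for linear
# regression: independent oracle for the Gibbs sampler
conjugate_posterior <- function(y, X, prior_sd = 10, a0 = 1e-3, b0 = 1e-3) {
  V0inv <- diag(1 / prior_sd^2, ncol(X))
  Vn <- solve(crossprod(X) + V0inv)
  mn <- Vn %*% crossprod(X, y)
  an <- a0 + length(y) / 2
  bn <- b0 + 0.5 * (sum(y^2) - t(mn) %*% (crossprod(X) + V0inv) %*% mn)
  list(mean = as.vector(mn),
       sd = sqrt(diag(Vn) * as.numeric(bn) / (an - 1)))
}

# exact posterior for the sampler's actual model (Normal coefficients,
# half-Cauchy residual SD): conditional conjugate closed form given sigma,
# integrated over sigma by quadrature
quadrature_posterior <- function(y, X, prior_sd = 10, hc_scale = 1,
                                 n_grid = 4000) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  lsig <- seq(-4, 4, length.out = n_grid)
  sig <- exp(lsig)
  logw <- numeric(n_grid)
  means <- matrix(NA_real_, n_grid, p)
  vars <- matrix(NA_real_, n_grid, p)
  for (g in seq_len(n_grid)) {
    s2 <- sig[g]^2
    P <- XtX / s2 + diag(1 / prior_sd^2, p)
    cP <- chol(P)
    mu <- backsolve(cP, forwardsolve(t(cP), Xty / s2))
    means[g, ] <- mu
    vars[g, ] <- diag(chol2inv(cP))
    # log marginal of y given sigma (beta integrated out), + prior on sigma,
    # + Jacobian for the log-sigma grid
    quad <- sum(y^2) / s2 - sum(mu * (P %*% mu))
    logdet <- 2 * sum(log(diag(cP)))
    logw[g] <- -0.5 * n * log(2 * pi * s2) - 0.5 * logdet -
      p * log(prior_sd) - 0.5 * quad +
      stats::dcauchy(sig[g], 0, hc_scale, log = TRUE) + lsig[g]
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  post_mean <- colSums(w * means)
  post_var <- colSums(w * (vars + means^2)) - post_mean^2
  list(mean = post_mean, sd = sqrt(post_var))
}

# Monte-Carlo standard errors from pooled draws of one parameter
mcse_mean <- function(draws_mat) {
  sd(as.vector(draws_mat)) / sqrt(ess_draws(draws_mat))
}
mcse_sd <- function(draws_mat) {
  sd(as.vector(draws_mat)) * sqrt(0.5 / ess_draws(draws_mat))
}
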