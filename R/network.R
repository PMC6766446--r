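# Bayesian network layer: the joint model factorizes into conditionally
# independent generalized linear regressions (all parents are observed), so
# each node is sampled on its own. Linear nodes use a conjugate Gibbs sampler
# (normal coefficients, half-Cauchy residual SD via an inverse-gamma
# mixture); logistic nodes use Gibbs with Polya-Gamma augmentation. Every
# non-root node carries site dummy variables.

#' MCMC settings for the network sampler
#'
#' @param n_chains number of chains (>= 2, initialized overdispersed).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param prior_sd SD of the Normal(0, prior_sd^2) coefficient prior on the
#'   standardized scale.
#' @param hc_scale scale of the half-Cauchy prior on linear-node residual SD.
#' @param method `"pg"` (Polya-Gamma Gibbs) or `"metropolis"` (random-walk
#'   fallback) for logistic nodes.
#' @param seed master seed; node and chain substreams are derived from it.
#' @param rhat_max,ess_min convergence gates used by [diagnostics_report()].
#' @return an `eed_mcmc_config` object.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 5000, n_burnin = 2500,
                        thin = 1, prior_sd = 10, hc_scale = 1,
                        method = c("pg", "metropolis"), seed = 1L,
                        rhat_max = 1.01, ess_min = 400) {
  method <- match.arg(method)
  stopifnot(n_iter > n_burnin, n_chains >= 2, thin >= 1, prior_sd > 0)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, prior_sd = prior_sd, hc_scale = hc_scale,
                 method = method, seed = as.integer(seed),
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "eed_mcmc_config")
}

#' Construct a network specification from explicit nodes and arcs
#'
#' Lower-level constructor for custom graphs (e.g. reduced models in
#' sensitivity or decomposition analyses). Arcs must respect the layer order
#' implied by node roles: `diet` (exposures, no parents) < `mediator` /
#' `inflammation` < `outcome` < `anemia`.
#'
#' @param nodes data frame `name`, `family` (`linear`/`logistic`), `role`.
#' @param arcs data frame `parent`, `child`.
#' @param site_ref reference site for the dummy coding (default: first level
#'   in the data at fit time).
#' @return an `eed_network` specification.
#' @export
network_spec <- function(nodes, arcs, site_ref = NULL) {
  stopifnot(all(c("name", "family", "role") %in% names(nodes)),
            all(c("parent", "child") %in% names(arcs)))
  stopifnot(all(nodes$family %in% c("linear", "logistic")),
            all(nodes$role %in% c("diet", "mediator", "inflammation",
                                  "outcome", "anemia")))
  layer <- c(diet = 1L, mediator = 2L, inflammation = 2L, outcome = 3L,
             anemia = 4L)[nodes$role]
  names(layer) <- nodes$name
  unknown <- setdiff(c(arcs$parent, arcs$child), nodes$name)
  if (length(unknown)) stop("arc references unknown node(s): ",
                            paste(unique(unknown), collapse = ", "))
  bad <- layer[arcs$parent] >= layer[arcs$child]
  if (any(bad)) {
    stop("arc(s) violate the layer order: ",
         paste(arcs$parent[bad], "->", arcs$child[bad], collapse = "; "))
  }
  if (any(arcs$child %in% nodes$name[nodes$role == "diet"])) {
    stop("diet nodes cannot have parents")
  }
  structure(list(nodes = nodes,
                 arcs = data.frame(parent = as.character(arcs$parent),
                                   child = as.character(arcs$child)),
                 site_ref = site_ref),
            class = "eed_network")
}

#' Build the default study network
#'
#' Enumerates the a-priori DAG: every diet density points at every EED
#' biomarker, at systemic inflammation (ln AGP), and at every deficiency
#' outcome; every EED biomarker and AGP point at every outcome; and the four
#' deficiency outcomes point at anemia. Folate and vitamin C are excluded
#' from the default diet set (dropped ahead of the multivariable model in the
#' emulated analysis).
#'
#' @param diet_vars diet exposures retained in the multivariable model.
#' @param mediators EED biomarker nodes.
#' @param outcomes binary deficiency outcomes (besides anemia).
#' @param include_anemia_parents add the deficiency -> anemia arcs.
#' @param site_ref reference site for dummy coding.
#' @return an `eed_network` specification.
#' @export
build_network <- function(diet_vars = c("iron", "zinc", "calcium", "vit_a",
                                        "vit_b6", "vit_b12", "protein"),
                          mediators = MEDIATOR_VARS,
                          outcomes = OUTCOME_VARS,
                          include_anemia_parents = TRUE,
                          site_ref = NULL) {
  nodes <- rbind(
    if (length(diet_vars)) data.frame(name = diet_vars, family = "linear",
                                      role = "diet"),
    data.frame(name = mediators, family = "linear", role = "mediator"),
    data.frame(name = INFLAMMATION_VAR, family = "linear",
               role = "inflammation"),
    data.frame(name = outcomes, family = "logistic", role = "outcome"),
    data.frame(name = ANEMIA_VAR, family = "logistic", role = "anemia"))
  cross <- function(p, ch) {
    if (!length(p) || !length(ch)) return(NULL)
    expand.grid(parent = p, child = ch, stringsAsFactors = FALSE)
  }
  arcs <- rbind(
    cross(diet_vars, c(mediators, INFLAMMATION_VAR)),
    cross(diet_vars, c(outcomes, ANEMIA_VAR)),
    cross(mediators, c(outcomes, ANEMIA_VAR)),
    cross(INFLAMMATION_VAR, c(outcomes, ANEMIA_VAR)),
    if (include_anemia_parents) cross(outcomes, ANEMIA_VAR))
  network_spec(nodes, arcs, site_ref = site_ref)
}

# design matrix for one node: intercept + parents + site dummies
node_design <- function(analytic, parents, site_ref) {
  site <- factor(analytic$site)
  if (!is.null(site_ref)) site <- stats::relevel(site, ref = site_ref)
  X <- matrix(1, nrow(analytic), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(parents)) {
    P <- as.matrix(analytic[, parents, drop = FALSE])
    colnames(P) <- parents
    X <- cbind(X, P)
  }
  if (nlevels(site) > 1) {
    S <- stats::model.matrix(~site)[, -1, drop = FALSE]
    colnames(S) <- paste0("site:", levels(site)[-1])
    X <- cbind(X, S)
  }
  X
}

#' Sample the posterior of a single generalized linear node
#'
#' @param y response (continuous, or 0/1 for logistic).
#' @param X design matrix (including intercept and any site dummies).
#' @param family `"linear"` or `"logistic"`.
#' @param mcmc an [mcmc_config()].
#' @param stream integer offset used to derive chain seeds.
#' @return list with `beta` (array kept-iterations x parameters x chains) and,
#'   for linear nodes, `sigma` (matrix kept-iterations x chains).
#' @export
fit_bayes_glm <- function(y, X, family = c("linear", "logistic"),
                          mcmc = mcmc_config(), stream = 0L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  p <- ncol(X)
  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  beta <- array(NA_real_, c(n_keep, p, mcmc$n_chains),
                dimnames = list(NULL, colnames(X), NULL))
  sigma <- if (family == "linear") matrix(NA_real_, n_keep, mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(substream_seed(mcmc$seed, stream * 131L + ch))
    beta0 <- rnorm(p, 0, 1)
    if (family == "linear") {
      out <- cpp_gibbs_linear(y, X, mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
                              mcmc$prior_sd, mcmc$hc_scale, beta0,
                              runif(1, 0.5, 2))
      beta[, , ch] <- out$beta
      sigma[, ch] <- out$sigma
    } else if (mcmc$method == "pg") {
      out <- cpp_gibbs_logistic(y, X, mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
                                mcmc$prior_sd, beta0)
      beta[, , ch] <- out$beta
    } else {
      beta[, , ch] <- rwm_logistic(y, X, mcmc, beta0)
    }
  }
  list(beta = beta, sigma = sigma)
}

# random-walk Metropolis fallback for logistic nodes: joint Gaussian proposal
# scaled from the Laplace approximation at the ML fit
rwm_logistic <- function(y, X, mcmc, beta0) {
  p <- ncol(X)
  ml <- suppressWarnings(glm.fit(X, y, family = binomial()))
  eta_ml <- X %*% ml$coefficients
  w <- as.vector(plogis(eta_ml) * (1 - plogis(eta_ml)))
  H <- crossprod(X * sqrt(w)) + diag(1 / mcmc$prior_sd^2, p)
  L <- t(chol(solve(H))) * (2.38 / sqrt(p))
  logpost <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(b^2) / (2 * mcmc$prior_sd^2)
  }
  b <- beta0
  lp <- logpost(b)
  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  out <- matrix(NA_real_, n_keep, p)
  k <- 0
  for (it in seq_len(mcmc$n_iter)) {
    cand <- b + as.vector(L %*% rnorm(p))
    lp_cand <- logpost(cand)
    if (log(runif(1)) < lp_cand - lp) {
      b <- cand
      lp <- lp_cand
    }
    if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0) {
      k <- k + 1
      out[k, ] <- b
    }
  }
  out
}

#' Fit the Bayesian network on an analytic dataset
#'
#' Samples each non-root node's regression independently (the factorization
#' implied by conditional independence given observed parents) and summarizes
#' every parameter: posterior mean, SD, equal-tailed 95% credibility
#' interval, odds-ratio scale for logistic nodes, split-Rhat, and effective
#' sample size.
#'
#' @param analytic complete-case, standardized analytic data frame with a
#'   `site` column.
#' @param spec an `eed_network` from [build_network()] / [network_spec()].
#' @param mcmc an [mcmc_config()].
#' @param extra_covariates optional extra columns (e.g. fever variables)
#'   added to the design of every logistic outcome node.
#' @return an object of class `eed_network_fit`: `summary` (one row per
#'   parameter; arc rows have `role == "arc"`), `draws` (per node), `spec`,
#'   `mcmc`.
#' @export
fit_network <- function(analytic, spec, mcmc = mcmc_config(),
                        extra_covariates = character(0)) {
  stopifnot(inherits(spec, "eed_network"), inherits(mcmc, "eed_mcmc_config"))
  fit_nodes <- spec$nodes$name[spec$nodes$role != "diet"]
  miss <- setdiff(c(spec$nodes$name, extra_covariates), names(analytic))
  if (length(miss)) stop("analytic data lacks column(s): ",
                         paste(miss, collapse = ", "))
  draws <- list()
  rows <- list()
  for (ni in seq_along(fit_nodes)) {
    node <- fit_nodes[ni]
    fam <- spec$nodes$family[spec$nodes$name == node]
    parents <- spec$arcs$parent[spec$arcs$child == node]
    covs <- parents
    if (fam == "logistic" && length(extra_covariates)) {
      covs <- c(covs, extra_covariates)
    }
    X <- node_design(analytic, covs, spec$site_ref)
    y <- analytic[[node]]
    if (anyNA(y) || anyNA(X)) stop("missing values in node ", node,
                                   "; run complete-case selection first")
    if (fam == "logistic" &&
        (length(unique(y)) < 2)) stop("degenerate outcome ", node)
    # node stream derived from the node NAME, so fitting a node alone or
    # inside the full network yields identical draws for the same seed
    fit <- fit_bayes_glm(y, X, fam, mcmc, stream = sum(utf8ToInt(node)))
    draws[[node]] <- fit
    terms <- colnames(X)
    for (j in seq_along(terms)) {
      mat <- fit$beta[, j, ] # kept x chains
      pooled <- as.vector(mat)
      qs <- quantile(pooled, c(0.025, 0.975), names = FALSE)
      role <- "intercept"
      if (terms[j] %in% parents) role <- "arc"
      if (grepl("^site:", terms[j])) role <- "site"
      rows[[length(rows) + 1L]] <- data.frame(
        child = node, term = terms[j], role = role, family = fam,
        mean = mean(pooled), sd = sd(pooled), lo = qs[1], hi = qs[2],
        or = if (fam == "logistic") exp(mean(pooled)) else NA_real_,
        or_lo = if (fam == "logistic") exp(qs[1]) else NA_real_,
        or_hi = if (fam == "logistic") exp(qs[2]) else NA_real_,
        rhat = split_rhat(mat), ess = ess_draws(mat))
    }
    if (fam == "linear") {
      mat <- fit$sigma
      pooled <- as.vector(mat)
      qs <- quantile(pooled, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        child = node, term = "sigma", role = "scale", family = fam,
        mean = mean(pooled), sd = sd(pooled), lo = qs[1], hi = qs[2],
        or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
        rhat = split_rhat(mat), ess = ess_draws(mat))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  summary$converged <- summary$rhat <= mcmc$rhat_max & summary$ess >= mcmc$ess_min
  structure(list(summary = summary, draws = draws, spec = spec, mcmc = mcmc),
            class = "eed_network_fit")
}

#' Pooled posterior draws of one parameter
#'
#' @param fit an `eed_network_fit`.
#' @param child node name.
#' @param term parameter name (a parent, `"(Intercept)"`, a site dummy, or
#'   `"sigma"`).
#' @return numeric vector of post-burn-in draws pooled across chains.
#' @export
posterior_draws <- function(fit, child, term) {
  d <- fit$draws[[child]]
  if (is.null(d)) stop("no fitted node ", child)
  if (term == "sigma") return(as.vector(d$sigma))
  j <- match(term, dimnames(d$beta)[[2]])
  if (is.na(j)) stop("no parameter ", term, " in node ", child)
  as.vector(d$beta[, j, ])
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed on chains split in half.
#'
#' @param mat draws matrix, iterations x chains.
#' @return scalar Rhat.
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat) %/% 2
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain effective sample size using chain-averaged autocovariances and
#' Geyer's initial monotone positive sequence truncation.
#'
#' @param mat draws matrix, iterations x chains.
#' @return estimated effective sample size.
#' @export
ess_draws <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 4) return(NA_real_)
  acovs <- sapply(seq_len(m), function(ch) {
    stats::acf(mat[, ch], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acovs)
  W <- mean(apply(mat, 2, var))
  B <- if (m > 1) n * var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer: sum consecutive autocorrelation pairs (starting at lags 0+1) while
  # positive, enforcing monotone decrease
  pairs <- c()
  prev <- Inf
  k <- 0
  repeat {
    i1 <- 2 * k + 1
    i2 <- 2 * k + 2
    if (i2 > length(rho)) break
    pair <- rho[i1] + rho[i2]
    if (pair <= 0) break
    pair <- min(pair, prev)
    pairs <- c(pairs, pair)
    prev <- pair
    k <- k + 1
  }
  tau <- max(-1 + 2 * sum(pairs), 1e-8)
  (m * n) / tau
}

#' Extract the significant-arc set
#'
#' Arcs whose equal-tailed 95% credibility interval excludes the null (zero
#' on the linear / log-odds scale; equivalently one on the OR scale).
#' Non-converged parameters are excluded with a warning.
#'
#' @param fit an `eed_network_fit` (or its `summary` data frame).
#' @return data frame of significant arcs with `sign`, `magnitude`, `scale`.
#' @export
significant_arcs <- function(fit) {
  s <- if (inherits(fit, "eed_network_fit")) fit$summary else fit
  arcs <- s[s$role == "arc", , drop = FALSE]
  if (any(!arcs$converged)) {
    warning(sum(!arcs$converged), " arc parameter(s) flagged non-converged; ",
            "excluded from the significant-arc set")
    arcs <- arcs[arcs$converged, , drop = FALSE]
  }
  sig <- arcs$lo > 0 | arcs$hi < 0
  out <- arcs[sig, c("term", "child", "family", "mean", "lo", "hi",
                     "or", "or_lo", "or_hi"), drop = FALSE]
  names(out)[1] <- "parent"
  out$sign <- ifelse(out$mean > 0, 1L, -1L)
  out$magnitude <- abs(out$mean)
  out$scale <- ifelse(out$family == "logistic", "log-odds", "linear")
  rownames(out) <- NULL
  out
}

#' Convergence diagnostics table
#'
#' @param fit an `eed_network_fit`.
#' @return data frame of split-Rhat and effective sample size per parameter
#'   with a `pass` flag, plus an overall verdict in `attr(, "pass")`.
#' @export
diagnostics_report <- function(fit) {
  stopifnot(inherits(fit, "eed_network_fit"))
  if (fit$mcmc$n_chains < 2) stop("Rhat undefined with a single chain")
  d <- fit$summary[, c("child", "term", "rhat", "ess")]
  d$pass <- !is.na(d$rhat) & d$rhat <= fit$mcmc$rhat_max &
    d$ess >= fit$mcmc$ess_min
  attr(d, "pass") <- all(d$pass)
  d
}
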