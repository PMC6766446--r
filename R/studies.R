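# Simulation studies over the full pipeline: credible-interval coverage /
# false-positive calibration of the network sampler, and operating
# characteristics of the mediation verdict. Both run generate -> preprocess
# -> fit end to end on every replicate.
#
# Study conditions: 7 sites x 200 children (analytic n = 1400; no
# missingness, so the analytic sample equals the design size) and low
# within-child measurement noise, so that per-child means identify the
# latent standardized scale on which the ground-truth coefficients are
# defined. The realistic-noise defaults are exercised by the round-trip and
# calibration checks instead.

study_noise <- list(diet_recall = 0.1, fecal_month = 0.25, lm_test = 0.2)
no_missing <- list(recall = 0, stool = 0, lm = 0, blood = 0)

#' Ground truth with arcs planted in fixed effect-size classes
#'
#' Places standardized effects of |beta| 0.1 and 0.2 on diet -> biomarker
#' arcs and log odds of +/- ln(1.25) on biomarker/inflammation/deficiency ->
#' outcome arcs, leaving every other arc of the default network at zero.
#'
#' @return an `eed_truth`.
#' @export
coverage_truth <- function() {
  b1 <- 0.1
  b2 <- 0.2
  bl <- log(1.25)
  truth_dag(rbind(
    data.frame(parent = c("vit_a", "calcium", "protein", "zinc", "vit_b12",
                          "iron"),
               child = c("mpo", "aat", "mpo", "lmz", "aat", "neo"),
               beta = c(-b1, -b1, -b1, -b1, b1, b1)),
    data.frame(parent = c("vit_a", "calcium", "zinc", "vit_b6", "protein",
                          "vit_b12"),
               child = c("aat", "mpo", "agp", "neo", "aat", "mpo"),
               beta = c(-b2, -b2, -b2, b2, -b2, b2)),
    data.frame(parent = c("lmz", "mpo", "aat", "neo", "mpo", "lmz", "neo",
                          "aat", "agp", "iron", "low_ferritin", "high_tfr"),
               child = c("anemia", "anemia", "low_ferritin", "low_ferritin",
                         "high_tfr", "low_retinol", "low_retinol",
                         "low_zinc", "low_retinol", "low_ferritin",
                         "anemia", "anemia"),
               beta = c(bl, bl, bl, bl, -bl, bl, -bl, -bl, bl, -bl, bl, bl))))
}

#' Credible-interval coverage study of the network sampler
#'
#' Repeatedly simulates a cohort from [coverage_truth()], runs preprocessing
#' and the network fit, and records, for every arc of the default network,
#' whether the 95% credibility interval covers the generating coefficient
#' and whether the arc is flagged significant.
#'
#' @param n_reps number of replicates.
#' @param children_per_site cohort size per site.
#' @param mcmc an [mcmc_config()] template (its seed is re-derived per
#'   replicate).
#' @param seed master seed.
#' @return list `arcs` (per replicate x arc results), `coverage_by_class`
#'   (data frame keyed by |beta|), `null_significant_rate`.
#' @export
coverage_study <- function(n_reps = 50, children_per_site = 200,
                           mcmc = mcmc_config(n_chains = 2, n_iter = 1500,
                                              n_burnin = 300),
                           seed = 1L) {
  truth <- coverage_truth()
  tt <- truth_table(truth)
  spec <- build_network()
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(children_per_site = children_per_site,
                      noise = study_noise, missing_rates = no_missing,
                      seed = substream_seed(seed, r))
    co <- generate_cohort(cfg, truth)
    pp <- preprocess_cohort(co)
    mcmc$seed <- substream_seed(seed, 100000L + r)
    fit <- fit_network(pp$analytic, spec, mcmc)
    arcs <- fit$summary[fit$summary$role == "arc",
                        c("child", "term", "mean", "lo", "hi")]
    m <- merge(arcs, tt[, c("parent", "child", "beta_true")],
               by.x = c("term", "child"), by.y = c("parent", "child"),
               all.x = TRUE)
    m$beta_true[is.na(m$beta_true)] <- 0
    m$rep <- r
    m$covered <- m$lo <= m$beta_true & m$beta_true <= m$hi
    m$significant <- m$lo > 0 | m$hi < 0
    rows[[r]] <- m
  }
  arcs <- do.call(rbind, rows)
  cls <- round(abs(arcs$beta_true), 6)
  cov <- aggregate(list(coverage = arcs$covered), list(abs_beta = cls), mean)
  cov$n_checks <- as.vector(table(cls))
  list(arcs = arcs, coverage_by_class = cov,
       null_significant_rate = mean(arcs$significant[cls == 0]),
       n_reps = n_reps)
}

#' Operating characteristics of the mediation verdict
#'
#' Simulates either a fully mediated truth (diet -> LMZ -> deficiency, no
#' direct arc; zinc -> LMZ -0.6, LMZ -> low retinol 0.75 on the log-odds
#' scale, sized so the marginal association is detectable at n = 1400) or a
#' null truth, and on each replicate compares the univariate
#' (total) effect with the network (direct) effect for the zinc - low
#' retinol pair.
#'
#' @param n_reps number of replicates.
#' @param truth_kind `"full"` (fully mediated) or `"null"` (no arcs).
#' @param children_per_site cohort size per site.
#' @param mcmc an [mcmc_config()] template.
#' @param seed master seed.
#' @return list `verdicts` (per replicate), `full_rate`, `results`.
#' @export
mediation_study <- function(n_reps = 50, truth_kind = c("full", "null"),
                            children_per_site = 200,
                            mcmc = mcmc_config(n_chains = 2, n_iter = 1200,
                                               n_burnin = 600),
                            seed = 1L) {
  truth_kind <- match.arg(truth_kind)
  truth <- if (truth_kind == "full") {
    truth_dag(data.frame(parent = c("zinc", "lmz"),
                         child = c("lmz", "low_retinol"),
                         beta = c(-0.6, 0.75)))
  } else {
    null_truth()
  }
  # estimator's graph: diet -> mediator -> outcome WITH the direct arc, so
  # the direct effect is estimated, not assumed absent
  nodes <- data.frame(name = c("zinc", "lmz", "low_retinol", "agp"),
                      family = c("linear", "linear", "logistic", "linear"),
                      role = c("diet", "mediator", "outcome",
                               "inflammation"))
  arcs <- data.frame(parent = c("zinc", "lmz", "zinc", "agp"),
                     child = c("lmz", "low_retinol", "low_retinol",
                               "low_retinol"))
  spec <- network_spec(nodes, arcs)
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(children_per_site = children_per_site,
                      noise = study_noise, missing_rates = no_missing,
                      seed = substream_seed(seed, 200000L + r))
    co <- generate_cohort(cfg, truth)
    pp <- preprocess_cohort(co)
    total <- fit_univariate_binary(pp$analytic, "zinc", "low_retinol")
    mcmc$seed <- substream_seed(seed, 300000L + r)
    fit <- fit_network(pp$analytic, spec, mcmc)
    res <- total_vs_direct(total, fit)
    res$rep <- r
    rows[[r]] <- res
  }
  results <- do.call(rbind, rows)
  list(results = results, verdicts = results$verdict,
       full_rate = mean(results$verdict == "full"),
       n_reps = n_reps, truth_kind = truth_kind)
}
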