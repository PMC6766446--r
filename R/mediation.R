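# Mediation layer: compares total (EED-unadjusted) with direct (network)
# diet effects, computes product-of-coefficients indirect effects through the
# gut-function biomarkers, and runs the fever-covariate sensitivity refit.
#
# The qualitative verdict (significance appears/disappears) and the
# quantitative product-of-coefficients estimator are both reported; the
# latter is this package's formalization of the mediation estimand. Odds
# ratios are non-collapsible, so total = direct + sum(indirect) holds exactly
# only for linear chains.

#' Compare total and direct effects
#'
#' Joins the univariate (total, mixed-model) diet - outcome effects with the
#' network (direct, EED- and AGP-adjusted) arcs, both on the log-odds scale,
#' and issues a qualitative mediation verdict per pair: `"full"` when the
#' total CI excludes the null but the direct CrI does not, `"partial"` when
#' both exclude the null and |direct| < |total|, `"none"` otherwise.
#' Proportion attenuated (1 - direct/total) is reported only when the total
#' is significant and the two estimates share a sign.
#'
#' @param univariate the `binary` table from [univariate_screen()] (or a
#'   compatible data frame with `exposure`, `outcome`, `estimate`, `lo`,
#'   `hi`).
#' @param network an `eed_network_fit` or its summary.
#' @return data frame, one row per exposure-outcome pair present in both
#'   layers.
#' @export
total_vs_direct <- function(univariate, network) {
  s <- if (inherits(network, "eed_network_fit")) network$summary else network
  arcs <- s[s$role == "arc", , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(univariate))) {
    uv <- univariate[k, ]
    dn <- arcs[arcs$term == uv$exposure & arcs$child == uv$outcome, ]
    if (nrow(dn) != 1 || is.na(uv$estimate)) {
      skipped <- skipped + 1L
      next
    }
    tot_sig <- uv$lo > 0 | uv$hi < 0
    dir_sig <- dn$lo > 0 | dn$hi < 0
    verdict <- "none"
    if (tot_sig && !dir_sig) verdict <- "full"
    if (tot_sig && dir_sig && abs(dn$mean) < abs(uv$estimate)) {
      verdict <- "partial"
    }
    prop_att <- NA_real_
    if (tot_sig && sign(dn$mean) == sign(uv$estimate)) {
      prop_att <- 1 - dn$mean / uv$estimate
    }
    out[[length(out) + 1L]] <- data.frame(
      exposure = uv$exposure, outcome = uv$outcome,
      total = uv$estimate, total_lo = uv$lo, total_hi = uv$hi,
      direct = dn$mean, direct_lo = dn$lo, direct_hi = dn$hi,
      proportion_attenuated = prop_att, verdict = verdict)
  }
  if (skipped > 0) {
    message(skipped, " exposure-outcome pair(s) absent from one layer; skipped")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Product-of-coefficients indirect effects
#'
#' For every diet -> mediator -> outcome path in the network, multiplies the
#' two arc coefficients draw by draw (the node posteriors are independent
#' under the conditional-independence factorization) and summarizes the
#' product with a 95% credibility interval. The per-pair total indirect
#' effect is the per-draw sum over mediators.
#'
#' @param fit an `eed_network_fit`.
#' @param mediators mediator node names to enumerate.
#' @return list `paths` (one row per path) and `totals` (one row per
#'   exposure-outcome pair).
#' @export
indirect_effects <- function(fit, mediators = MEDIATOR_VARS) {
  stopifnot(inherits(fit, "eed_network_fit"))
  spec <- fit$spec
  meds <- intersect(mediators, spec$nodes$name)
  diet <- spec$nodes$name[spec$nodes$role == "diet"]
  outs <- spec$nodes$name[spec$nodes$role %in% c("outcome", "anemia")]
  has_arc <- function(p, ch) any(spec$arcs$parent == p & spec$arcs$child == ch)
  paths <- list()
  totals <- list()
  for (d in diet) {
    for (o in outs) {
      sum_draws <- NULL
      for (m in meds) {
        if (!has_arc(d, m) || !has_arc(m, o)) next
        prod_draws <- posterior_draws(fit, m, d) * posterior_draws(fit, o, m)
        qs <- quantile(prod_draws, c(0.025, 0.975), names = FALSE)
        paths[[length(paths) + 1L]] <- data.frame(
          exposure = d, mediator = m, outcome = o,
          indirect = mean(prod_draws), lo = qs[1], hi = qs[2])
        sum_draws <- if (is.null(sum_draws)) prod_draws else
          sum_draws + prod_draws
      }
      if (!is.null(sum_draws)) {
        qs <- quantile(sum_draws, c(0.025, 0.975), names = FALSE)
        totals[[length(totals) + 1L]] <- data.frame(
          exposure = d, outcome = o, indirect_total = mean(sum_draws),
          lo = qs[1], hi = qs[2])
      }
    }
  }
  list(paths = do.call(rbind, paths), totals = do.call(rbind, totals))
}

#' Total / direct / indirect decomposition for one exposure-outcome pair
#'
#' Fits the full network and a reduced model (outcome on exposure and site
#' only, same family) and reports total, direct, and summed indirect effects.
#' For all-linear graphs the path-tracing identity total = direct +
#' sum(indirect) holds up to Monte-Carlo error; for logistic outcomes the
#' decomposition is approximate (odds-ratio non-collapsibility).
#'
#' @param analytic standardized analytic data frame.
#' @param spec the full `eed_network` specification.
#' @param exposure,outcome node names.
#' @param mcmc an [mcmc_config()].
#' @param mediators mediator names for the indirect enumeration.
#' @return one-row data frame `total`, `direct`, `indirect_sum`, `gap`
#'   (total - direct - indirect_sum).
#' @export
path_decomposition <- function(analytic, spec, exposure, outcome,
                               mcmc = mcmc_config(),
                               mediators = MEDIATOR_VARS) {
  full <- fit_network(analytic, spec, mcmc)
  fam <- spec$nodes$family[spec$nodes$name == outcome]
  red_nodes <- data.frame(
    name = c(exposure, outcome), family = c("linear", fam),
    role = c("diet", if (fam == "logistic") "outcome" else "mediator"))
  red <- network_spec(red_nodes,
                      data.frame(parent = exposure, child = outcome),
                      site_ref = spec$site_ref)
  total_fit <- fit_network(analytic, red, mcmc)
  ts <- total_fit$summary
  total <- ts$mean[ts$role == "arc"]
  fs <- full$summary
  dr <- fs$mean[fs$role == "arc" & fs$term == exposure & fs$child == outcome]
  direct <- if (length(dr)) dr else 0
  ind <- indirect_effects(full, mediators)
  it <- ind$totals
  isum <- it$indirect_total[it$exposure == exposure & it$outcome == outcome]
  if (!length(isum)) isum <- 0
  data.frame(exposure = exposure, outcome = outcome, total = total,
             direct = direct, indirect_sum = isum,
             gap = total - direct - isum)
}

#' Fever-covariate sensitivity refit
#'
#' Refits the network's binary outcome nodes with the three fever variables
#' (proportion of days with fever, fever within 7 days before / after the
#' blood draw) added as additional markers of systemic inflammation, and
#' compares arc coefficients side by side.
#'
#' @param analytic standardized analytic data frame including the fever
#'   columns.
#' @param spec the `eed_network` specification.
#' @param mcmc an [mcmc_config()].
#' @param fever_vars fever column names.
#' @return list `comparison` (per-arc base and refit means with `shift`),
#'   `max_shift`, `fever_terms` (posterior summary of the fever
#'   coefficients), `base`, `refit` (the two fits).
#' @export
sensitivity_fever <- function(analytic, spec, mcmc = mcmc_config(),
                              fever_vars = c("fever_frac", "fever_prior7",
                                             "fever_post7")) {
  missing_cols <- setdiff(fever_vars, names(analytic))
  if (length(missing_cols)) {
    stop("fever column(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  keep <- vapply(fever_vars, function(v) {
    sd(analytic[[v]]) > 0
  }, logical(1))
  if (any(!keep)) {
    warning("dropping degenerate fever column(s): ",
            paste(fever_vars[!keep], collapse = ", "))
  }
  fever_vars <- fever_vars[keep]
  if (!length(fever_vars)) stop("no usable fever columns remain")
  base <- fit_network(analytic, spec, mcmc)
  refit <- fit_network(analytic, spec, mcmc, extra_covariates = fever_vars)
  ab <- base$summary[base$summary$role == "arc",
                     c("child", "term", "mean", "lo", "hi")]
  ar <- refit$summary[refit$summary$role == "arc",
                      c("child", "term", "mean", "lo", "hi")]
  comparison <- merge(ab, ar, by = c("child", "term"),
                      suffixes = c("_base", "_fever"))
  comparison$shift <- comparison$mean_fever - comparison$mean_base
  fever_terms <- refit$summary[refit$summary$term %in% fever_vars, ]
  list(comparison = comparison, max_shift = max(abs(comparison$shift)),
       fever_terms = fever_terms, base = base, refit = refit)
}
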