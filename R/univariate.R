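# Univariate screening layer: one exposure at a time, mixed models with site
# as a random intercept. Binary deficiency outcomes give odds ratios per 1 SD
# (adjusted for ln AGP); continuous EED/inflammation biomarkers give mean
# effects per 1 SD. Inference is by Wald 95% CIs; no multiplicity adjustment.

#' Univariate mixed-model screen for a binary outcome
#'
#' Fits `outcome ~ exposure + agp + (1 | site)` by logistic mixed model and
#' reports the odds ratio per 1 SD of the (standardized) exposure with a Wald
#' 95% CI.
#'
#' @param data analytic data frame (standardized exposures, 0/1 outcomes,
#'   `site` column).
#' @param exposure,outcome column names.
#' @param adjust_agp include standardized ln AGP as a covariate (the default,
#'   matching the screen for deficiency outcomes); ignored when the exposure
#'   is AGP itself.
#' @return one-row data frame of class `eed_univariate`: estimate (log-odds),
#'   `or`, CI bounds, `n`, `converged`.
#' @export
fit_univariate_binary <- function(data, exposure, outcome, adjust_agp = TRUE) {
  stopifnot(length(unique(data$site)) >= 2)
  covs <- exposure
  if (adjust_agp && exposure != "agp") covs <- c(covs, "agp")
  f <- as.formula(paste(outcome, "~", paste(covs, collapse = " + "),
                        "+ (1 | site)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(f, data = data, family = binomial()))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(exposure = exposure, outcome = outcome,
                      family = "logistic", estimate = NA_real_, se = NA_real_,
                      lo = NA_real_, hi = NA_real_, or = NA_real_,
                      or_lo = NA_real_, or_hi = NA_real_,
                      n = nrow(data), converged = FALSE))
  }
  b <- lme4::fixef(fit)[exposure]
  se <- wald_se(fit, exposure)
  conv <- mermod_converged(fit)
  data.frame(exposure = exposure, outcome = outcome, family = "logistic",
             estimate = unname(b), se = unname(se),
             lo = unname(b - 1.96 * se), hi = unname(b + 1.96 * se),
             or = exp(unname(b)), or_lo = exp(unname(b - 1.96 * se)),
             or_hi = exp(unname(b + 1.96 * se)),
             n = nrow(data), converged = conv)
}

#' Univariate mixed-model screen for a continuous biomarker
#'
#' Fits `biomarker ~ exposure + (1 | site)` by linear mixed model (REML) and
#' reports the mean effect per 1 SD with a Wald 95% CI.
#'
#' @param data analytic data frame.
#' @param exposure,biomarker standardized column names.
#' @return one-row data frame: estimate, CI bounds, `n`, `converged`.
#' @export
fit_univariate_continuous <- function(data, exposure, biomarker) {
  stopifnot(length(unique(data$site)) >= 2)
  f <- as.formula(paste(biomarker, "~", exposure, "+ (1 | site)"))
  fit <- tryCatch(suppressMessages(suppressWarnings(lme4::lmer(f, data = data))),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(exposure = exposure, outcome = biomarker,
                      family = "linear", estimate = NA_real_, se = NA_real_,
                      lo = NA_real_, hi = NA_real_, or = NA_real_,
                      or_lo = NA_real_, or_hi = NA_real_,
                      n = nrow(data), converged = FALSE))
  }
  b <- lme4::fixef(fit)[exposure]
  se <- wald_se(fit, exposure)
  conv <- mermod_converged(fit)
  data.frame(exposure = exposure, outcome = biomarker, family = "linear",
             estimate = unname(b), se = unname(se),
             lo = unname(b - 1.96 * se), hi = unname(b + 1.96 * se),
             or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
             n = nrow(data), converged = conv)
}

# Wald SE of one fixed effect; NA on degenerate fits (e.g. zero residual
# variance), where the point estimate is still meaningful
wald_se <- function(fit, term) {
  tryCatch(suppressWarnings(unname(sqrt(diag(as.matrix(vcov(fit)))[term]))),
           error = function(e) NA_real_)
}

# boundary (singular) fits count as converged; genuine optimizer failures do
# not
mermod_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  opt_ok && !any(grepl("failed to converge", msgs))
}

#' Run the full univariate screen
#'
#' Screens every exposure (diet densities and EED biomarkers) against every
#' binary deficiency outcome, and every diet density against every
#' continuous biomarker, reproducing the layout of the study's screening
#' tables. A `significant` star marks CIs excluding the null.
#'
#' @param analytic standardized analytic data frame.
#' @param diet_vars diet exposures to screen.
#' @param eed_vars continuous biomarker exposures/outcomes.
#' @param outcomes binary deficiency outcomes.
#' @return list `binary` (OR table) and `continuous` (mean-effect table).
#' @export
univariate_screen <- function(analytic,
                              diet_vars = intersect(DIET_VARS, names(analytic)),
                              eed_vars = c(MEDIATOR_VARS, INFLAMMATION_VAR),
                              outcomes = c(ANEMIA_VAR, OUTCOME_VARS)) {
  bin <- list()
  for (x in c(diet_vars, setdiff(eed_vars, INFLAMMATION_VAR))) {
    for (o in outcomes) {
      bin[[paste(x, o)]] <- fit_univariate_binary(analytic, x, o)
    }
  }
  bin <- do.call(rbind, bin)
  bin$significant <- !is.na(bin$lo) & (bin$lo > 0 | bin$hi < 0)
  cont <- list()
  for (x in diet_vars) {
    for (y in eed_vars) {
      cont[[paste(x, y)]] <- fit_univariate_continuous(analytic, x, y)
    }
  }
  cont <- do.call(rbind, cont)
  cont$significant <- !is.na(cont$lo) & (cont$lo > 0 | cont$hi < 0)
  rownames(bin) <- rownames(cont) <- NULL
  list(binary = bin, continuous = cont)
}

#' Within-site Spearman correlation with bootstrap CI
#'
#' Computes Spearman's rho within each site, averages across sites, and
#' attaches a percentile bootstrap CI from resampling children within site.
#'
#' @param data data frame with a `site` column.
#' @param var1,var2 column names.
#' @param n_boot bootstrap resamples.
#' @return one-row data frame `rho`, `lo`, `hi`, `n`.
#' @export
correlation_summary <- function(data, var1, var2, n_boot = 1000) {
  sites <- split(data[, c(var1, var2)], data$site)
  sites <- sites[vapply(sites, nrow, integer(1)) >= 10]
  if (length(sites) == 0) stop("need at least 10 children in some site")
  site_rho <- function(d, idx = seq_len(nrow(d))) {
    suppressWarnings(cor(d[[var1]][idx], d[[var2]][idx], method = "spearman",
                         use = "complete.obs"))
  }
  rho <- mean(vapply(sites, site_rho, numeric(1)))
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(vapply(sites, function(d) {
      site_rho(d, sample.int(nrow(d), replace = TRUE))
    }, numeric(1)))
  }, numeric(1))
  data.frame(var1 = var1, var2 = var2, rho = rho,
             lo = quantile(boots, 0.025, names = FALSE),
             hi = quantile(boots, 0.975, names = FALSE),
             n = sum(vapply(sites, nrow, integer(1))))
}
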