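#' Simulation configuration for a synthetic multi-site cohort
#'
#' Bundles the design of the simulated study: which sites to include, how many
#' children per site, the measurement schedule, within-child noise, and
#' missingness. Site-level magnitudes (means and SDs of the transformed
#' observables, deficiency prevalences, altitudes) come from calibration
#' tables bundled with the package, which emulate a published 7-site infant
#' cohort spanning South America, Africa, and South Asia.
#'
#' @param sites character vector of site codes to simulate (subset of the
#'   seven calibrated sites: BGD, INV, NEB, PKN, BRF, PEL, TZH).
#' @param children_per_site number of children per site; a scalar is recycled,
#'   `NULL` uses the calibrated per-site sample sizes.
#' @param months ages (months) at which dietary recalls are collected.
#' @param stool_ages ages (months) of non-diarrheal stool collections
#'   (at most 5).
#' @param lm_test_ages ages (months) of the dual-sugar permeability tests.
#' @param noise within-child noise SDs: `diet_recall` (relative, in pooled-SD
#'   units of each sqrt-density), `fecal_month` (ln units), `lm_test`
#'   (z units). Month-to-month variance components are not reported for the
#'   emulated cohort; these defaults are the package's own choice.
#' @param diet_corr exchangeable correlation of the within-site nutrient
#'   density latents.
#' @param missing_rates per-stream probability that an observation is missing:
#'   `recall`, `stool`, `lm`, `blood`.
#' @param agp_distortion named vector of inflammation-distortion slopes
#'   (per unit ln AGP above a low-inflammation reference) applied to observed
#'   blood concentrations; names among `ferritin`, `retinol`, `zinc`, `tfr`.
#'   Default 0 (no distortion), so the observed concentrations classify back
#'   exactly to the simulated deficiency states.
#' @param fever_agp_coef dependence of fever variables on the ln-AGP latent
#'   (log-odds / logit-scale units).
#' @param seed master seed; every child draws from a deterministic substream
#'   derived from it, so results do not depend on iteration order.
#' @return an object of class `eed_sim_config`.
#' @export
sim_config <- function(sites = NULL,
                       children_per_site = NULL,
                       months = 9:15,
                       stool_ages = c(9, 10, 11, 12, 15),
                       lm_test_ages = c(9, 15),
                       noise = list(diet_recall = 0.25, fecal_month = 0.6,
                                    lm_test = 0.45),
                       diet_corr = 0.4,
                       missing_rates = list(recall = 0.05, stool = 0.10,
                                            lm = 0.05, blood = 0.05),
                       agp_distortion = c(ferritin = 0, retinol = 0,
                                          zinc = 0, tfr = 0),
                       fever_agp_coef = 0.3,
                       seed = 1L) {
  info <- read.csv(eed_extdata("site_info.csv"), stringsAsFactors = FALSE)
  calib <- read.csv(eed_extdata("site_calibration.csv"),
                    stringsAsFactors = FALSE)
  prev <- read.csv(eed_extdata("site_prevalence.csv"),
                   stringsAsFactors = FALSE)

  if (is.null(sites)) sites <- info$site
  if (!all(sites %in% info$site)) {
    stop("unknown site(s): ", paste(setdiff(sites, info$site), collapse = ", "))
  }
  info <- info[match(sites, info$site), , drop = FALSE]
  if (!is.null(children_per_site)) {
    info$n_children <- rep_len(children_per_site, nrow(info))
  }
  stopifnot(all(info$n_children > 0), length(stool_ages) <= 5,
            length(months) >= 1, length(lm_test_ages) >= 1)
  mr <- unlist(missing_rates)
  if (any(mr < 0 | mr > 1)) stop("missing_rates must lie in [0, 1]")
  calib <- calib[calib$site %in% sites, , drop = FALSE]
  prev <- prev[prev$site %in% sites, , drop = FALSE]

  structure(list(sites = info, calibration = calib, prevalence = prev,
                 months = months, stool_ages = stool_ages,
                 lm_test_ages = lm_test_ages, noise = noise,
                 diet_corr = diet_corr, missing_rates = missing_rates,
                 agp_distortion = agp_distortion,
                 fever_agp_coef = fever_agp_coef,
                 seed = as.integer(seed)),
            class = "eed_sim_config")
}

#' Ground-truth DAG for the simulator
#'
#' Defines the data-generating graph on the standardized scale the estimators
#' report: each arc carries a standardized coefficient (per 1 SD of the
#' transformed parent), on the identity scale for linear children and the
#' log-odds scale for binary children. Arcs must respect the a-priori layer
#' order diet -> {MPO, NEO, AAT, LMZ, AGP} -> deficiency outcomes -> anemia.
#'
#' @param arcs data frame with columns `parent`, `child`, `beta`.
#' @param prevalence optional data frame `site`, `outcome`, `prevalence`
#'   giving per-site marginal targets for the binary outcomes; defaults to the
#'   calibrated targets.
#' @return an object of class `eed_truth`.
#' @export
truth_dag <- function(arcs, prevalence = NULL) {
  stopifnot(is.data.frame(arcs),
            all(c("parent", "child", "beta") %in% names(arcs)))
  arcs$parent <- as.character(arcs$parent)
  arcs$child <- as.character(arcs$child)
  if (nrow(arcs)) {
    lp <- node_layer(arcs$parent)
    lc <- node_layer(arcs$child)
    bad <- lp >= lc
    if (any(bad)) {
      stop("arc(s) violate the layer order (graph would not be acyclic): ",
           paste(arcs$parent[bad], "->", arcs$child[bad], collapse = "; "))
    }
    if (anyDuplicated(paste(arcs$parent, arcs$child))) {
      stop("duplicated arcs in truth DAG")
    }
  }
  if (is.null(prevalence)) {
    prevalence <- read.csv(eed_extdata("site_prevalence.csv"),
                           stringsAsFactors = FALSE)
  }
  arcs$family <- node_family(arcs$child)
  structure(list(arcs = arcs, prevalence = prevalence), class = "eed_truth")
}

#' Default ground truth emulating the study conditions
#'
#' Arc coefficients are set to magnitudes typical of the emulated cohort:
#' modest negative diet -> EED effects (standardized -0.08 to -0.21), EED ->
#' deficiency log-odds around |ln OR| 0.15-0.3, direct diet -> outcome
#' effects for iron, and strong deficiency -> anemia arcs.
#'
#' @return an `eed_truth` object.
#' @export
default_truth <- function() {
  arcs <- rbind(
    # diet -> EED biomarkers / systemic inflammation (linear, standardized)
    data.frame(parent = "vit_a",   child = "mpo", beta = -0.12),
    data.frame(parent = "vit_a",   child = "neo", beta = -0.14),
    data.frame(parent = "vit_a",   child = "aat", beta = -0.21),
    data.frame(parent = "calcium", child = "mpo", beta = -0.15),
    data.frame(parent = "calcium", child = "neo", beta = -0.08),
    data.frame(parent = "calcium", child = "aat", beta = -0.19),
    data.frame(parent = "zinc",    child = "aat", beta = -0.15),
    data.frame(parent = "zinc",    child = "lmz", beta = -0.14),
    data.frame(parent = "zinc",    child = "agp", beta = -0.13),
    data.frame(parent = "protein", child = "mpo", beta = -0.12),
    data.frame(parent = "protein", child = "aat", beta = -0.14),
    data.frame(parent = "vit_b12", child = "aat", beta = -0.19),
    data.frame(parent = "vit_b12", child = "mpo", beta =  0.08),
    # EED -> deficiency (log-odds per 1 SD)
    data.frame(parent = "lmz", child = "anemia",       beta = log(1.15)),
    data.frame(parent = "mpo", child = "anemia",       beta = log(1.16)),
    data.frame(parent = "aat", child = "low_ferritin", beta = log(1.19)),
    data.frame(parent = "neo", child = "low_ferritin", beta = log(1.22)),
    data.frame(parent = "mpo", child = "high_tfr",     beta = log(0.86)),
    data.frame(parent = "lmz", child = "low_retinol",  beta = log(1.24)),
    data.frame(parent = "neo", child = "low_retinol",  beta = log(0.75)),
    data.frame(parent = "aat", child = "low_zinc",     beta = log(0.83)),
    # direct diet -> deficiency
    data.frame(parent = "iron",    child = "low_ferritin", beta = log(0.73)),
    data.frame(parent = "iron",    child = "high_tfr",     beta = log(0.79)),
    data.frame(parent = "iron",    child = "low_retinol",  beta = log(0.74)),
    data.frame(parent = "calcium", child = "high_tfr",     beta = log(1.28)),
    data.frame(parent = "vit_a",   child = "anemia",       beta = log(1.52)),
    # systemic inflammation -> deficiency
    data.frame(parent = "agp", child = "low_retinol",  beta = log(1.58)),
    data.frame(parent = "agp", child = "high_tfr",     beta = log(1.18)),
    data.frame(parent = "agp", child = "anemia",       beta = log(1.29)),
    data.frame(parent = "agp", child = "low_ferritin", beta = log(0.62)),
    # deficiency -> anemia
    data.frame(parent = "low_ferritin", child = "anemia", beta = log(2.79)),
    data.frame(parent = "low_retinol",  child = "anemia", beta = log(1.58)),
    data.frame(parent = "high_tfr",     child = "anemia", beta = log(2.26)),
    data.frame(parent = "low_zinc",     child = "anemia", beta = log(0.93))
  )
  truth_dag(arcs)
}

#' Null ground truth (all arcs absent)
#'
#' @return an `eed_truth` with no arcs; outcomes are driven only by the
#'   per-site prevalence targets.
#' @export
null_truth <- function() {
  truth_dag(data.frame(parent = character(), child = character(),
                       beta = numeric()))
}

#' Tabulate the arcs of a ground-truth DAG
#'
#' @param truth an `eed_truth` object.
#' @return data frame with one row per arc: `parent`, `child`, `family`,
#'   `beta_true`, and `or_true = exp(beta_true)` for logistic children.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "eed_truth"))
  out <- truth$arcs
  names(out)[names(out) == "beta"] <- "beta_true"
  out$or_true <- ifelse(out$family == "logistic", exp(out$beta_true), NA_real_)
  out[, c("parent", "child", "family", "beta_true", "or_true")]
}
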