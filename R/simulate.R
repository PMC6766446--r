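# Synthetic cohort generation.
#
# Latent-first design: each child gets pooled-standardized latent values for
# the transformed diet densities, EED biomarkers, LMZ and ln AGP (the exact
# scale on which the network reports effects), binary deficiency states are
# drawn from the ground-truth arcs on the log-odds scale, and the observable
# streams (monthly recalls, stool assays, dual-sugar tests, blood panel) are
# back-transformed from the latents with site shifts and within-child noise.
# Running the preprocessing module on the output therefore approximately
# recovers the latents, so recovery tests are exact in expectation.

# internal constants of the dual-sugar back-transformation (reference-scale
# intercept/age/sex structure and the mapping from z units to ln recovery)
LM_CONST <- list(
  man_intercept = 0.8,  man_age = 0.04,  man_sex = -0.06, man_scale = 0.7,
  ratio_intercept = -2.0, ratio_age = -0.02, ratio_sex = 0.03,
  ratio_scale = 0.8
)

# spreads (log scale unless noted) of the concentration draws around each
# deficiency threshold, conditional on the simulated binary state
BLOOD_SPREAD <- c(retinol = 0.45, zinc = 0.25, ferritin = 0.9, tfr = 0.5)
HB_SPREAD <- 1.3 # g/dL, additive

#' Generate a synthetic multi-site cohort from a known ground truth
#'
#' @param config an [sim_config()] object.
#' @param truth an [truth_dag()] / [default_truth()] object.
#' @return an object of class `eed_cohort`: a list of tidy data frames
#'   (`children`, `recalls`, `stool`, `lm`, `blood`, `latents`) plus the
#'   `truth` and `config` used. `latents` holds the ground-truth standardized
#'   variables and binary states each child was generated from.
#' @details Deterministic given `config$seed`: each child's draws come from a
#'   substream seeded by a counter, so the output is independent of iteration
#'   order and byte-identical across calls.
#' @export
generate_cohort <- function(config, truth = default_truth()) {
  stopifnot(inherits(config, "eed_sim_config"), inherits(truth, "eed_truth"))

  sites <- config$sites
  calib <- config$calibration
  n_sites <- nrow(sites)

  # pooled location/scale and per-site standardized deviations per observable
  cal_vars <- unique(calib$variable)
  pool <- lapply(cal_vars, function(v) {
    sub <- calib[calib$variable == v, ]
    sub <- sub[match(sites$site, sub$site), ]
    pool_sites(sub$mean, sub$sd, sites$n_children)
  })
  names(pool) <- cal_vars

  # per-site outcome prevalence targets
  prev <- config$prevalence
  outcomes <- c(OUTCOME_VARS, ANEMIA_VAR)
  prev_mat <- sapply(outcomes, function(o) {
    sub <- prev[prev$outcome == o, ]
    sub$prevalence[match(sites$site, sub$site)]
  })
  rownames(prev_mat) <- sites$site
  # restrict truth prevalence overrides if provided
  if (!is.null(truth$prevalence)) {
    tp <- truth$prevalence
    for (k in seq_len(nrow(tp))) {
      if (tp$site[k] %in% rownames(prev_mat) && tp$outcome[k] %in% outcomes) {
        prev_mat[tp$site[k], tp$outcome[k]] <- tp$prevalence[k]
      }
    }
  }

  arcs <- truth$arcs
  parents_of <- function(node) arcs[arcs$child == node, , drop = FALSE]
  latent_nodes <- c(MEDIATOR_VARS, INFLAMMATION_VAR)

  # average within-site SD in pooled units, per diet nutrient (for residual
  # variance bookkeeping of child latents)
  w <- sites$n_children / sum(sites$n_children)
  avg_within <- sapply(DIET_VARS, function(nm) {
    sum(w * pool[[calib_variable(nm)]]$within_sd)
  })

  # residual SD of a latent node given its diet-parent contribution, per site
  resid_sd_node <- function(node, pa) {
    p <- pool[[calib_variable(node)]]
    if (nrow(pa) == 0) return(p$within_sd)
    aw <- avg_within[pa$parent]
    b <- pa$beta
    vb <- sum((b * aw)^2)
    if (length(b) > 1) {
      cp <- outer(b * aw, b * aw)
      vb <- vb + config$diet_corr * (sum(cp) - sum(diag(cp)))
    }
    sqrt(pmax(0.05, p$within_sd^2 - vb))
  }
  resid_sds <- lapply(latent_nodes, function(m) resid_sd_node(m, parents_of(m)))
  names(resid_sds) <- latent_nodes

  mr <- config$missing_rates
  months <- config$months
  n_mon <- length(months)
  ref_ln_agp <- pool[["ln_agp"]]$center + pool[["ln_agp"]]$scale * qnorm(0.10)

  # pre-allocated accumulators (matrix-based for speed; assembled into tidy
  # data frames at the end)
  n_tot <- sum(sites$n_children)
  ch_id <- ch_site <- ch_sex <- character(n_tot)
  ch_num <- matrix(NA_real_, n_tot, 4,
                   dimnames = list(NULL, c("breastfed_prop", "fever_frac",
                                           "fever_prior7", "fever_post7")))
  lat_names <- c(DIET_VARS, latent_nodes, "z_manz",
                 paste0("d_", outcomes))
  lat <- matrix(NA_real_, n_tot, length(lat_names),
                dimnames = list(NULL, lat_names))
  blood_mat <- matrix(NA_real_, n_tot, 6,
                      dimnames = list(NULL, c("hemoglobin", "retinol",
                                              "ferritin", "tfr", "zinc",
                                              "agp")))
  recalls <- list(); stool <- list(); lmrows <- list()
  rec_ids <- list(); stool_ids <- list(); lm_ids <- list()
  ctr <- 0L
  for (s in seq_len(n_sites)) {
    site <- sites$site[s]
    alt_corr <- altitude_correction(sites$altitude_m[s])
    pe <- calib[calib$variable == "energy_kcal" & calib$site == site, ]
    pc <- calib[calib$variable == "carb_pcte" & calib$site == site, ]
    for (i in seq_len(sites$n_children[s])) {
      ctr <- ctr + 1L
      set.seed(substream_seed(config$seed, ctr))
      id <- sprintf("%s-%04d", site, i)
      sex <- if (runif(1) < 0.5) "female" else "male"
      sexm <- as.numeric(sex == "male")

      # --- latent standardized variables ------------------------------
      z <- numeric(0)
      g0 <- rnorm(1)
      u <- sqrt(config$diet_corr) * g0 +
        sqrt(1 - config$diet_corr) * rnorm(length(DIET_VARS))
      for (k in seq_along(DIET_VARS)) {
        p <- pool[[calib_variable(DIET_VARS[k])]]
        z[DIET_VARS[k]] <- p$dev[s] + p$within_sd[s] * u[k]
      }
      for (m in latent_nodes) {
        p <- pool[[calib_variable(m)]]
        pa <- parents_of(m)
        shift <- 0
        if (nrow(pa)) {
          pdev <- sapply(pa$parent,
                         function(q) pool[[calib_variable(q)]]$dev[s])
          shift <- sum(pa$beta * (z[pa$parent] - pdev))
        }
        z[m] <- p$dev[s] + shift + rnorm(1, 0, resid_sds[[m]][s])
      }
      pm <- pool[["manz"]]
      z_manz <- pm$dev[s] + pm$within_sd[s] * rnorm(1)

      # --- binary deficiency states -----------------------------------
      d <- numeric(0)
      for (o in outcomes) { # anemia last: may depend on the others
        pa <- parents_of(o)
        eta <- logit(prev_mat[s, o])
        if (nrow(pa)) {
          for (k in seq_len(nrow(pa))) {
            pnode <- pa$parent[k]
            if (pnode %in% outcomes) {
              eta <- eta + pa$beta[k] * (d[pnode] - prev_mat[s, pnode])
            } else {
              pdev <- pool[[calib_variable(pnode)]]$dev[s]
              eta <- eta + pa$beta[k] * (z[pnode] - pdev)
            }
          }
        }
        d[o] <- rbinom(1, 1, inv_logit(eta))
      }

      # --- observables -------------------------------------------------
      ln_agp_val <- pool[["ln_agp"]]$center + pool[["ln_agp"]]$scale * z["agp"]

      # monthly recalls
      keep <- runif(n_mon) >= mr$recall
      if (any(keep)) {
        mk <- months[keep]
        energy <- pmax(60, rnorm(length(mk), pe$mean, pe$sd))
        dens <- sapply(DIET_VARS, function(nm) {
          p <- pool[[calib_variable(nm)]]
          dv <- p$center + p$scale * z[nm] +
            rnorm(length(mk), 0, config$noise$diet_recall * p$scale)
          pmax(0.02, dv)
        })
        if (length(mk) == 1) dens <- matrix(dens, nrow = 1,
                                            dimnames = list(NULL, DIET_VARS))
        amounts <- dens^2 * energy / 1000
        carb_pct <- pmin(80, pmax(30, rnorm(length(mk), pc$mean, pc$sd)))
        prot_pct <- 0.4 * dens[, "protein"]^2
        fat_pct <- pmax(5, 100 - carb_pct - prot_pct)
        # renormalize so the three macronutrients account for all energy
        tot <- carb_pct + prot_pct + fat_pct
        amounts[, "protein"] <- (prot_pct / tot) * energy / 4
        recalls[[ctr]] <- cbind(age_mo = mk, energy_kcal = energy,
                                carb_g = (carb_pct / tot) * energy / 4,
                                fat_g = (fat_pct / tot) * energy / 9,
                                amounts)
        rec_ids[[ctr]] <- rep(id, length(mk))
      }

      # stool assays
      keep <- runif(length(config$stool_ages)) >= mr$stool
      if (any(keep)) {
        sa <- config$stool_ages[keep]
        nv <- config$noise$fecal_month
        stool[[ctr]] <- cbind(
          age_mo = sa,
          mpo = exp(pool[["ln_mpo"]]$center + pool[["ln_mpo"]]$scale * z["mpo"] +
                      rnorm(length(sa), 0, nv)),
          neo = exp(pool[["ln_neo"]]$center + pool[["ln_neo"]]$scale * z["neo"] +
                      rnorm(length(sa), 0, nv)),
          aat = exp(pool[["ln_aat"]]$center + pool[["ln_aat"]]$scale * z["aat"] +
                      rnorm(length(sa), 0, nv)))
        stool_ids[[ctr]] <- rep(id, length(sa))
      }

      # dual-sugar tests
      keep <- runif(length(config$lm_test_ages)) >= mr$lm
      if (any(keep)) {
        la <- config$lm_test_ages[keep]
        v_lmz <- pool[["lmz"]]$center + pool[["lmz"]]$scale * z["lmz"]
        v_man <- pm$center + pm$scale * z_manz
        ln_man <- LM_CONST$man_intercept + LM_CONST$man_age * (la - 12) +
          LM_CONST$man_sex * sexm +
          LM_CONST$man_scale * (v_man + rnorm(length(la), 0, config$noise$lm_test))
        ln_ratio <- LM_CONST$ratio_intercept + LM_CONST$ratio_age * (la - 12) +
          LM_CONST$ratio_sex * sexm +
          LM_CONST$ratio_scale * (v_lmz + rnorm(length(la), 0, config$noise$lm_test))
        lmrows[[ctr]] <- cbind(age_mo = la, lac_rec = exp(ln_ratio + ln_man),
                               man_rec = exp(ln_man))
        lm_ids[[ctr]] <- rep(id, length(la))
      }

      # blood panel at 15 mo, consistent with the simulated binary states
      conc <- c(
        retinol = draw_conc(d["low_retinol"], 0.70, "<", BLOOD_SPREAD["retinol"]),
        zinc = draw_conc(d["low_zinc"], 9.9, "<", BLOOD_SPREAD["zinc"]),
        ferritin = draw_conc(d["low_ferritin"], 12, "<", BLOOD_SPREAD["ferritin"]),
        tfr = draw_conc(d["high_tfr"], 8.3, ">", BLOOD_SPREAD["tfr"]))
      for (an in names(config$agp_distortion)) {
        dd <- config$agp_distortion[[an]]
        if (an %in% names(conc) && dd != 0) {
          conc[an] <- conc[an] * exp(dd * max(0, ln_agp_val - ref_ln_agp))
        }
      }
      hb_margin <- 0.05 + abs(rnorm(1, 0, HB_SPREAD))
      hb_adj <- if (d["anemia"] == 1) 11.0 - hb_margin else 11.0 + hb_margin
      bl <- c(hemoglobin = max(3, hb_adj) + alt_corr,
              retinol = conc[["retinol"]], ferritin = conc[["ferritin"]],
              tfr = conc[["tfr"]], zinc = conc[["zinc"]],
              agp = exp(ln_agp_val))
      bl[runif(6) < mr$blood] <- NA_real_
      blood_mat[ctr, ] <- bl

      # fever surveillance
      med <- max(0.005, sites$fever_frac_median[s])
      fev_p <- inv_logit(logit(0.15) + config$fever_agp_coef * z["agp"])
      ch_id[ctr] <- id
      ch_site[ctr] <- site
      ch_sex[ctr] <- sex
      ch_num[ctr, ] <- c(stats::rbeta(1, 9, 1),
                         inv_logit(logit(med) + config$fever_agp_coef *
                                     z["agp"] + rnorm(1, 0, 0.6)),
                         rbinom(1, 1, fev_p), rbinom(1, 1, fev_p))
      lat[ctr, ] <- c(z, z_manz, d)
    }
  }

  as_stream <- function(mats, ids) {
    if (!length(mats)) return(NULL)
    out <- as.data.frame(do.call(rbind, mats))
    cbind(child_id = unlist(ids), out)
  }
  structure(list(
    children = cbind(data.frame(child_id = ch_id, site = ch_site,
                                sex = ch_sex), as.data.frame(ch_num)),
    recalls = as_stream(recalls, rec_ids),
    stool = as_stream(stool, stool_ids),
    lm = as_stream(lmrows, lm_ids),
    blood = cbind(data.frame(child_id = ch_id), as.data.frame(blood_mat)),
    latents = cbind(data.frame(child_id = ch_id, site = ch_site),
                    as.data.frame(lat)),
    truth = truth, config = config), class = "eed_cohort")
}

# concentration consistent with a binary deficiency state: lognormal spread
# away from the threshold, on the deficient side iff state == 1
draw_conc <- function(state, cut, dir, spread) {
  margin <- 0.02 + abs(rnorm(1, 0, spread))
  below <- (dir == "<") == (state == 1)
  cut * exp(if (below) -margin else margin)
}

#' Write a cohort to a directory of tidy CSV files
#'
#' Writes `children.csv`, `recalls.csv`, `stool.csv`, `lm.csv`, `blood.csv`,
#' `latents.csv` (synthetic ground-truth latents) and `truth.json`.
#'
#' @param cohort an `eed_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eed_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("children", "recalls", "stool", "lm", "blood", "latents")) {
    write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(truth_table(cohort$truth),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort back from a directory of CSV files
#'
#' @param dir directory written by [write_cohort()] (or user CSVs following
#'   the same schema; `latents.csv` is optional).
#' @return an `eed_cohort` (without `truth`/`config` unless bundled).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  out <- list(children = rd("children.csv"), recalls = rd("recalls.csv"),
              stool = rd("stool.csv"), lm = rd("lm.csv"),
              blood = rd("blood.csv"), latents = rd("latents.csv"),
              truth = NULL, config = NULL)
  if (is.null(out$children)) stop("children.csv not found in ", dir)
  structure(out, class = "eed_cohort")
}
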