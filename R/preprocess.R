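# Preprocessing: raw longitudinal streams -> standardized analytic dataset.
#
# Transform order is fixed throughout: square root (diet densities) and
# natural log (biomarkers) are applied per observation, then averaged within
# child, then standardized over the pooled analytic sample.

#' Summarize one child's dietary recalls
#'
#' Computes the mean over recalls of the square-root nutrient densities
#' (\eqn{\sqrt{1000 \cdot \mathrm{amount} / \mathrm{energy}}}) together with
#' the percent of energy from carbohydrate, protein, and fat. The square root
#' is taken per recall, before averaging.
#'
#' @param recalls data frame of recalls for a single child with columns
#'   `energy_kcal`, `carb_g`, `fat_g`, and one amount column per nutrient.
#' @param nutrients nutrient column names to summarize.
#' @return one-row data frame of mean sqrt densities, `%E` columns,
#'   and `n_recalls`; `NULL` if no recall has positive energy.
#' @export
summarize_diet <- function(recalls, nutrients = intersect(DIET_VARS,
                                                          names(recalls))) {
  ok <- !is.na(recalls$energy_kcal) & recalls$energy_kcal > 0
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " recall(s) with nonpositive energy")
    recalls <- recalls[ok, , drop = FALSE]
  }
  if (nrow(recalls) == 0) return(NULL)
  e <- recalls$energy_kcal
  dens <- lapply(nutrients, function(nm) {
    mean(sqrt(1000 * recalls[[nm]] / e))
  })
  names(dens) <- nutrients
  prot_e <- 100 * 4 * recalls$protein / e
  carb_e <- 100 * 4 * recalls$carb_g / e
  fat_e <- 100 * 9 * recalls$fat_g / e
  cbind(data.frame(dens), data.frame(
    carb_pcte = mean(carb_e), protein_pcte = mean(prot_e),
    fat_pcte = mean(fat_e), n_recalls = nrow(recalls)))
}

#' Summarize one child's fecal biomarkers
#'
#' Natural log per sample, then the arithmetic mean over samples.
#'
#' @param stool data frame for one child with columns `mpo`, `neo`, `aat`.
#' @return one-row data frame `mpo`, `neo`, `aat` (mean ln concentrations)
#'   and `n_stool`; `NULL` when no usable sample remains.
#' @export
summarize_fecal <- function(stool) {
  vals <- as.matrix(stool[, c("mpo", "neo", "aat"), drop = FALSE])
  bad <- rowSums(!is.na(vals) & vals <= 0) > 0
  if (any(bad)) {
    warning("rejecting ", sum(bad), " stool record(s) with nonpositive ",
            "concentration")
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0) return(NULL)
  m <- colMeans(log(vals), na.rm = TRUE)
  data.frame(mpo = m[["mpo"]], neo = m[["neo"]], aat = m[["aat"]],
             n_stool = nrow(vals))
}

#' Fit the internal dual-sugar reference model
#'
#' Regresses the log percent urinary recovery of each sugar (and of their
#' ratio) on age and sex over a designated reference stratum. The fitted
#' predictions and residual SDs define the z-scores used downstream, so a
#' child at the reference expectation scores 0 by construction.
#'
#' @param tests data frame of reference-stratum tests with columns `age_mo`,
#'   `sex` (`"female"`/`"male"`), `lac_rec`, `man_rec` (percent recovery).
#' @param min_n minimum number of usable reference tests.
#' @return an object of class `eed_lm_reference`.
#' @export
fit_lm_reference <- function(tests, min_n = 30) {
  tests <- tests[!is.na(tests$lac_rec) & !is.na(tests$man_rec) &
                   tests$lac_rec > 0 & tests$man_rec > 0, , drop = FALSE]
  if (nrow(tests) < min_n) {
    stop("need at least ", min_n, " reference tests, got ", nrow(tests))
  }
  if (length(unique(tests$age_mo)) < 2 || length(unique(tests$sex)) < 2) {
    stop("degenerate reference design: need both sexes and at least two ages")
  }
  sexm <- as.numeric(tests$sex == "male")
  fit_one <- function(y) {
    fit <- lm(y ~ tests$age_mo + sexm)
    list(coef = unname(coef(fit)), sigma = summary(fit)$sigma)
  }
  structure(list(lac = fit_one(log(tests$lac_rec)),
                 man = fit_one(log(tests$man_rec)),
                 ratio = fit_one(log(tests$lac_rec / tests$man_rec)),
                 n = nrow(tests)),
            class = "eed_lm_reference")
}

ref_predict <- function(part, age_mo, sexm) {
  part$coef[1] + part$coef[2] * age_mo + part$coef[3] * sexm
}

#' Dual-sugar z-scores for one child
#'
#' Per test, the z-score of each sugar is the log observed recovery minus the
#' reference prediction, divided by the reference residual SD; `lmz` is
#' computed the same way on the log lactulose:mannitol ratio. The child value
#' is the mean over available tests; a test missing one sugar contributes
#' only its defined scores.
#'
#' @param tests data frame for one child: `age_mo`, `lac_rec`, `man_rec`.
#' @param ref an [fit_lm_reference()] object.
#' @param sex the child's sex (`"female"` or `"male"`).
#' @return one-row data frame `lacz`, `manz`, `lmz`, `n_lm`.
#' @export
lm_zscores <- function(tests, ref, sex = "female") {
  stopifnot(inherits(ref, "eed_lm_reference"))
  if (nrow(tests) == 0) return(NULL)
  sexm <- as.numeric(sex == "male")
  lac <- ifelse(!is.na(tests$lac_rec) & tests$lac_rec > 0, tests$lac_rec, NA)
  man <- ifelse(!is.na(tests$man_rec) & tests$man_rec > 0, tests$man_rec, NA)
  z_lac <- (log(lac) - ref_predict(ref$lac, tests$age_mo, sexm)) / ref$lac$sigma
  z_man <- (log(man) - ref_predict(ref$man, tests$age_mo, sexm)) / ref$man$sigma
  z_lmz <- (log(lac / man) - ref_predict(ref$ratio, tests$age_mo, sexm)) /
    ref$ratio$sigma
  if (all(is.na(z_lmz)) && all(is.na(z_lac)) && all(is.na(z_man))) return(NULL)
  data.frame(lacz = mean(z_lac, na.rm = TRUE), manz = mean(z_man, na.rm = TRUE),
             lmz = mean(z_lmz, na.rm = TRUE),
             n_lm = sum(!is.na(z_lmz)))
}

#' Altitude adjustment of hemoglobin
#'
#' Subtracts the expected altitude-driven increase in hemoglobin using the
#' standard polynomial correction
#' \eqn{-0.032 a + 0.022 a^2} g/dL with \eqn{a} = altitude in thousands of
#' feet, applied above 3000 ft; below that the value is unchanged. The
#' correction is floored at zero, so adjustment never increases hemoglobin.
#'
#' @param hb hemoglobin, g/dL.
#' @param altitude_m altitude in meters (recycled).
#' @return adjusted hemoglobin, g/dL.
#' @export
adjust_hemoglobin_altitude <- function(hb, altitude_m) {
  if (any(!is.na(hb) & hb < 0)) stop("negative hemoglobin")
  if (any(altitude_m < 0)) stop("negative altitude")
  hb - altitude_correction(altitude_m)
}

altitude_correction <- function(altitude_m) {
  a <- altitude_m * 3.28084 / 1000 # thousands of feet
  corr <- ifelse(a > 3, -0.032 * a + 0.022 * a^2, 0)
  pmax(0, corr)
}

#' Classify micronutrient deficiency from a blood panel
#'
#' Applies the fixed clinical cutoffs with strict inequalities: anemia
#' hemoglobin < 11.0 g/dL (altitude-adjusted), low retinol < 0.70 umol/L,
#' low zinc < 9.9 umol/L, low ferritin < 12 ug/L, elevated transferrin
#' receptor > 8.3 mg/L, elevated AGP > 1 g/L. A missing analyte yields an
#' undefined (NA) flag, not `FALSE`.
#'
#' @param panel data frame with columns among `hemoglobin` (adjusted),
#'   `retinol`, `ferritin`, `tfr`, `zinc`, `agp`.
#' @return data frame of 0/1/NA flags `anemia`, `low_retinol`, `low_zinc`,
#'   `low_ferritin`, `high_tfr`, `elevated_agp`.
#' @export
classify_deficiency <- function(panel) {
  for (v in intersect(names(panel),
                      c("hemoglobin", "retinol", "ferritin", "tfr", "zinc",
                        "agp"))) {
    if (any(!is.na(panel[[v]]) & panel[[v]] < 0)) {
      stop("negative concentration in ", v)
    }
  }
  out <- lapply(DEFICIENCY_THRESHOLDS, function(th) {
    x <- panel[[th$analyte]]
    if (is.null(x)) return(rep(NA_integer_, nrow(panel)))
    if (th$dir == "<") as.integer(x < th$cut) else as.integer(x > th$cut)
  })
  as.data.frame(out)
}

#' Inflammation adjustment of a biomarker distribution (regression method)
#'
#' Regression-corrects a micronutrient biomarker for systemic inflammation on
#' the log scale: \eqn{\tilde c = \exp(\ln c - \hat\beta (\ln AGP -
#' \ln AGP_{ref}))}, with the slope estimated from the sample and the
#' reference taken at the lowest decile of ln AGP. Only observations above
#' the reference are adjusted. Used solely for prevalence reporting; the
#' network consumes unadjusted values.
#'
#' @param conc biomarker concentrations.
#' @param ln_agp ln AGP, same length.
#' @param analyte label used in messages.
#' @param ref_ln_agp low-inflammation reference; default the 10th percentile
#'   of `ln_agp`.
#' @param min_n minimum observations needed to estimate the slope; below it
#'   the data are returned unadjusted with a warning.
#' @return adjusted concentrations, with the estimated slope in
#'   `attr(, "slope")`.
#' @export
adjust_inflammation_brinda <- function(conc, ln_agp, analyte = "analyte",
                                       ref_ln_agp = NULL, min_n = 50) {
  ok <- !is.na(conc) & !is.na(ln_agp) & conc > 0
  if (sum(ok) < min_n) {
    warning("fewer than ", min_n, " observations for ", analyte,
            "; skipping inflammation adjustment")
    out <- conc
    attr(out, "slope") <- NA_real_
    return(out)
  }
  if (is.null(ref_ln_agp)) ref_ln_agp <- quantile(ln_agp[ok], 0.10, names = FALSE)
  slope <- unname(coef(lm(log(conc[ok]) ~ ln_agp[ok]))[2])
  out <- conc
  adj <- ok & ln_agp > ref_ln_agp
  out[adj] <- exp(log(conc[adj]) - slope * (ln_agp[adj] - ref_ln_agp))
  attr(out, "slope") <- slope
  out
}

#' Standardize columns to mean 0, SD 1
#'
#' @param x data frame or matrix of numeric columns.
#' @return list with `x` (standardized data frame), `center`, `scale`
#'   (SD with denominator n-1), for back-transformation of effects.
#' @export
standardize <- function(x) {
  x <- as.data.frame(x)
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, sd, numeric(1))
  if (any(scale == 0 | is.na(scale))) {
    stop("constant column(s): ",
         paste(names(x)[scale == 0 | is.na(scale)], collapse = ", "))
  }
  out <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              x, center, scale, SIMPLIFY = FALSE))
  list(x = out, center = center, scale = scale)
}

#' Complete-case selection
#'
#' @param rows data frame.
#' @param required variables that must be non-missing.
#' @return list `data` (retained rows) and `exclusions` (dropped-children
#'   counts by site and by missing variable).
#' @export
complete_cases <- function(rows, required) {
  stopifnot(all(required %in% names(rows)))
  miss <- sapply(required, function(v) is.na(rows[[v]]))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nrow(rows))
  keep <- rowSums(miss) == 0
  if (!any(keep)) stop("complete-case selection removed every row")
  by_var <- colSums(miss)
  names(by_var) <- required
  by_site <- if ("site" %in% names(rows)) {
    tapply(!keep, rows$site, sum)
  } else NULL
  list(data = rows[keep, , drop = FALSE],
       exclusions = list(n_dropped = sum(!keep),
                         by_variable = by_var[by_var > 0],
                         by_site = by_site))
}

#' Preprocess a cohort into the standardized analytic dataset
#'
#' Runs the full preprocessing chain: per-child diet summaries (sqrt density
#' before averaging), per-child mean ln fecal biomarkers, the internally
#' fitted dual-sugar reference and per-child z-scores, altitude adjustment of
#' hemoglobin, deficiency classification, complete-case selection, and
#' standardization of the continuous model variables over the analytic
#' sample. Inflammation-adjusted prevalences are computed separately and do
#' not feed the model variables.
#'
#' @param cohort an `eed_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param required variables a child must have to enter the analytic sample.
#' @param site_info data frame `site`, `altitude_m`, `is_reference`; default
#'   the bundled table.
#' @return list with `analytic` (standardized model-ready rows), `scaling`,
#'   `prevalence` (inflammation-adjusted and unadjusted, by site),
#'   `exclusions`, `lm_reference`, and `summaries` (unstandardized child
#'   summaries).
#' @export
preprocess_cohort <- function(cohort,
                              required = c(DIET_VARS, "mpo", "neo", "aat",
                                           "lmz", "agp", "anemia",
                                           "low_ferritin", "high_tfr",
                                           "low_retinol", "low_zinc"),
                              site_info = NULL) {
  stopifnot(inherits(cohort, "eed_cohort"))
  if (is.null(site_info)) {
    site_info <- if (!is.null(cohort$config)) cohort$config$sites else
      read.csv(eed_extdata("site_info.csv"), stringsAsFactors = FALSE)
  }
  ch <- cohort$children

  # vectorized equivalents of summarize_diet() / summarize_fecal() /
  # lm_zscores(): same transforms and filters, computed cohort-wide
  mean_by <- function(mat, ids) {
    counts <- rowsum((!is.na(mat)) * 1, ids)
    sums <- rowsum(mat, ids, na.rm = TRUE)
    out <- as.data.frame(sums / counts)
    out$child_id <- rownames(sums)
    out
  }

  r <- cohort$recalls
  bad_e <- is.na(r$energy_kcal) | r$energy_kcal <= 0
  if (any(bad_e)) {
    warning("excluding ", sum(bad_e), " recall(s) with nonpositive energy")
    r <- r[!bad_e, , drop = FALSE]
  }
  nutr <- intersect(DIET_VARS, names(r))
  dens <- sqrt(1000 * as.matrix(r[, nutr, drop = FALSE]) / r$energy_kcal)
  dmat <- cbind(dens,
                carb_pcte = 100 * 4 * r$carb_g / r$energy_kcal,
                protein_pcte = 100 * 4 * r$protein / r$energy_kcal,
                fat_pcte = 100 * 9 * r$fat_g / r$energy_kcal)
  diet <- mean_by(dmat, r$child_id)
  diet$n_recalls <- as.vector(rowsum(rep(1L, nrow(r)), r$child_id))

  st <- cohort$stool
  vals <- as.matrix(st[, c("mpo", "neo", "aat"), drop = FALSE])
  bad_s <- rowSums(!is.na(vals) & vals <= 0) > 0
  if (any(bad_s)) {
    warning("rejecting ", sum(bad_s), " stool record(s) with nonpositive ",
            "concentration")
    vals <- vals[!bad_s, , drop = FALSE]
    st <- st[!bad_s, , drop = FALSE]
  }
  fecal <- mean_by(log(vals), st$child_id)
  fecal$n_stool <- as.vector(rowsum(rep(1L, nrow(st)), st$child_id))

  # dual-sugar reference: fitted on the designated reference site
  ref_site <- site_info$site[site_info$is_reference == 1][1]
  if (is.na(ref_site)) stop("no reference site flagged in site_info")
  lm_tests <- merge(cohort$lm, ch[, c("child_id", "site", "sex")],
                    by = "child_id")
  ref_fit <- fit_lm_reference(lm_tests[lm_tests$site == ref_site, ])
  sexm <- as.numeric(lm_tests$sex == "male")
  lac <- ifelse(!is.na(lm_tests$lac_rec) & lm_tests$lac_rec > 0,
                lm_tests$lac_rec, NA)
  man <- ifelse(!is.na(lm_tests$man_rec) & lm_tests$man_rec > 0,
                lm_tests$man_rec, NA)
  zmat <- cbind(
    lacz = (log(lac) - ref_predict(ref_fit$lac, lm_tests$age_mo, sexm)) /
      ref_fit$lac$sigma,
    manz = (log(man) - ref_predict(ref_fit$man, lm_tests$age_mo, sexm)) /
      ref_fit$man$sigma,
    lmz = (log(lac / man) - ref_predict(ref_fit$ratio, lm_tests$age_mo, sexm)) /
      ref_fit$ratio$sigma)
  lmz <- mean_by(zmat, lm_tests$child_id)
  lmz$n_lm <- as.vector(rowsum(as.integer(!is.na(zmat[, "lmz"])),
                               lm_tests$child_id))

  # blood panel: altitude-adjust hemoglobin, classify with strict cutoffs
  blood <- merge(cohort$blood, ch[, c("child_id", "site")], by = "child_id")
  alt <- site_info$altitude_m[match(blood$site, site_info$site)]
  blood$hb_adj <- adjust_hemoglobin_altitude(blood$hemoglobin, alt)
  panel <- data.frame(hemoglobin = blood$hb_adj, retinol = blood$retinol,
                      ferritin = blood$ferritin, tfr = blood$tfr,
                      zinc = blood$zinc, agp = blood$agp)
  flags <- classify_deficiency(panel)
  blood <- cbind(blood, flags)
  blood$ln_agp <- ifelse(!is.na(blood$agp) & blood$agp > 0,
                         log(blood$agp), NA_real_)

  panel_cols <- blood[, c("child_id", "hb_adj", "retinol", "ferritin", "tfr",
                          "zinc", "agp", "ln_agp", "anemia", "low_ferritin",
                          "high_tfr", "low_retinol", "low_zinc",
                          "elevated_agp")]
  names(panel_cols)[2:7] <- c("hb_adj", "retinol_conc", "ferritin_conc",
                              "tfr_conc", "zinc_conc", "agp_conc")
  rows <- Reduce(function(a, b) merge(a, b, by = "child_id", all = TRUE),
                 list(ch, diet, fecal, lmz, panel_cols))
  rows$agp <- rows$ln_agp # the model's inflammation variable is ln AGP

  cc <- complete_cases(rows, required)
  analytic <- cc$data

  std_vars <- c(DIET_VARS, "mpo", "neo", "aat", "lmz", "agp")
  std <- standardize(analytic[, std_vars])
  analytic[, std_vars] <- std$x

  prevalence <- prevalence_table(blood)

  list(analytic = analytic,
       scaling = data.frame(variable = std_vars, center = std$center,
                            scale = std$scale, row.names = NULL),
       prevalence = prevalence,
       exclusions = cc$exclusions,
       lm_reference = ref_fit,
       summaries = list(diet = diet, fecal = fecal, lmz = lmz, blood = blood))
}

# site-level prevalence, unadjusted and after the regression-based
# inflammation adjustment of ferritin, retinol, zinc, and TfR
prevalence_table <- function(blood) {
  adj <- blood
  for (an in c("ferritin", "retinol", "zinc", "tfr")) {
    adj[[an]] <- suppressWarnings(
      adjust_inflammation_brinda(blood[[an]], blood$ln_agp, analyte = an))
  }
  adj_flags <- classify_deficiency(
    data.frame(hemoglobin = adj$hb_adj, retinol = adj$retinol,
               ferritin = adj$ferritin, tfr = adj$tfr, zinc = adj$zinc,
               agp = adj$agp))
  out <- list()
  for (o in names(DEFICIENCY_THRESHOLDS)) {
    raw <- tapply(blood[[o]], blood$site, mean, na.rm = TRUE)
    ad <- tapply(adj_flags[[o]], blood$site, mean, na.rm = TRUE)
    out[[o]] <- data.frame(site = names(raw), outcome = o,
                           prevalence_unadjusted = as.numeric(raw),
                           prevalence_adjusted = as.numeric(ad),
                           row.names = NULL)
  }
  do.call(rbind, out)
}
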