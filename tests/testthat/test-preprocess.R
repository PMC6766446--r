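test_that("diet densities take the square root before averaging", {
  one <- data.frame(child_id = "c", age_mo = 9, energy_kcal = 500,
                    carb_g = 60, fat_g = 10, iron = 8, protein = 12)
  out <- summarize_diet(one, nutrients = "iron")
  expect_equal(out$iron, 4) # sqrt(1000 * 8 / 500) = sqrt(16)
  # densities 9 and 25 before sqrt -> mean of (3, 5) = 4, not sqrt(17)
  two <- data.frame(child_id = "c", age_mo = c(9, 10),
                    energy_kcal = c(1000, 1000), carb_g = 0, fat_g = 0,
                    iron = c(9, 25), protein = 0.1)
  out <- summarize_diet(two, nutrients = "iron")
  expect_equal(out$iron, 4)
  expect_false(isTRUE(all.equal(out$iron, sqrt(mean(c(9, 25))))))
  # zero-energy recalls are excluded with a warning
  mixed <- rbind(one, transform(one, energy_kcal = 0))
  expect_warning(out <- summarize_diet(mixed, nutrients = "iron"),
                 "nonpositive energy")
  expect_equal(out$n_recalls, 1)
})

test_that("fecal biomarkers are log-transformed before averaging", {
  st <- data.frame(child_id = "c", age_mo = c(9, 10),
                   mpo = c(exp(1), exp(1)), neo = c(1, exp(2)),
                   aat = c(exp(-1), exp(-3)))
  out <- summarize_fecal(st)
  expect_equal(out$mpo, 1)
  expect_equal(out$neo, 1) # mean(log(1), 2) = 1, not log(mean)
  expect_equal(out$aat, -2)
  expect_warning(out <- summarize_fecal(
    data.frame(child_id = "c", age_mo = 9:10, mpo = c(5, -1),
               neo = c(2, 2), aat = c(1, 1))), "nonpositive")
  expect_equal(out$n_stool, 1)
  expect_equal(out$mpo, log(5))
})

test_that("dual-sugar reference fit recovers known age and sex effects", {
  gen_ref <- function(b_age, b_sex, n = 300, seed = 2) {
    set.seed(seed)
    age <- sample(c(9, 15), n, replace = TRUE)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    sexm <- as.numeric(sex == "male")
    data.frame(age_mo = age, sex = sex,
               lac_rec = exp(-1.2 + b_age * age + b_sex * sexm +
                               rnorm(n, 0, 0.5)),
               man_rec = exp(0.8 + rnorm(n, 0, 0.4)))
  }
  # null age/sex effects -> slopes near zero
  ref0 <- fit_lm_reference(gen_ref(0, 0))
  expect_lt(abs(ref0$lac$coef[2]), 3 * 0.5 / sqrt(300) / sd(c(9, 15)))
  # known slopes recovered
  ref1 <- fit_lm_reference(gen_ref(0.05, -0.2, seed = 3))
  expect_lt(abs(ref1$lac$coef[2] - 0.05), 0.03)
  expect_lt(abs(ref1$lac$coef[3] + 0.2), 0.18)
  # z-scoring the reference stratum against itself: mean 0, SD ~ 1
  d <- gen_ref(0.05, -0.2, seed = 4)
  zs <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    lm_zscores(d[i, ], fit_lm_reference(d), sex = d$sex[i])
  }))
  expect_lt(abs(mean(zs$lacz)), 0.05)
  expect_lt(abs(sd(zs$lacz) - 1), 0.1)
  # degenerate designs are rejected
  d1 <- gen_ref(0, 0)
  d1$age_mo <- 9
  expect_error(fit_lm_reference(d1), "degenerate")
  expect_error(fit_lm_reference(gen_ref(0, 0)[1:5, ]), "at least")
})

test_that("dual-sugar z-scores average over tests and handle missing sugars", {
  ref <- structure(list(lac = list(coef = c(-1, 0, 0), sigma = 1),
                        man = list(coef = c(1, 0, 0), sigma = 1),
                        ratio = list(coef = c(-2, 0, 0), sigma = 0.5),
                        n = 100), class = "eed_lm_reference")
  # a test exactly at the reference prediction scores zero everywhere
  at_ref <- data.frame(age_mo = 9, lac_rec = exp(-1), man_rec = exp(1))
  z <- lm_zscores(at_ref, ref)
  expect_equal(unname(unlist(z[, c("lacz", "manz", "lmz")])), c(0, 0, 0))
  # two tests with LMZ 0.2 and 0.6 -> mean 0.4
  two <- data.frame(age_mo = c(9, 15),
                    man_rec = exp(1),
                    lac_rec = exp(-1 + 0.5 * c(0.2, 0.6)))
  expect_equal(lm_zscores(two, ref)$lmz, 0.4)
  # a missing sugar drops only the scores that need it
  part <- data.frame(age_mo = 9, lac_rec = exp(-0.5), man_rec = NA)
  z <- lm_zscores(part, ref)
  expect_equal(z$lacz, 0.5)
  expect_true(is.na(z$lmz))
})

test_that("altitude adjustment matches the published polynomial", {
  expect_equal(adjust_hemoglobin_altitude(11, 0), 11)
  expect_equal(adjust_hemoglobin_altitude(11, 500), 11) # below 3000 ft
  # independent evaluation of the correction at a sample altitude
  alt_m <- 1400
  a <- alt_m * 3.28084 / 1000
  expect_equal(adjust_hemoglobin_altitude(12, alt_m),
               12 - (-0.032 * a + 0.022 * a^2))
  # monotone nonincreasing in altitude
  alts <- seq(0, 4000, by = 250)
  adj <- adjust_hemoglobin_altitude(rep(12, length(alts)), alts)
  expect_true(all(diff(adj) <= 1e-12))
  expect_error(adjust_hemoglobin_altitude(-1, 0), "negative")
})

test_that("deficiency classification applies strict printed cutoffs", {
  panel <- data.frame(
    hemoglobin = c(11.0, 10.99, NA),
    retinol = c(0.70, 0.69, 0.71),
    ferritin = c(12, 11.99, 12.01),
    tfr = c(8.3, 8.31, 8.29),
    zinc = c(9.9, 9.89, 9.91),
    agp = c(1.0, 1.01, 0.99))
  f <- classify_deficiency(panel)
  expect_equal(f$anemia, c(0L, 1L, NA))
  expect_equal(f$low_retinol, c(0L, 1L, 0L))
  expect_equal(f$low_ferritin, c(0L, 1L, 0L))
  expect_equal(f$high_tfr, c(0L, 1L, 0L))
  expect_equal(f$low_zinc, c(0L, 1L, 0L))
  expect_equal(f$elevated_agp, c(0L, 1L, 0L))
  # monotone in each analyte, in the stated direction
  grid <- data.frame(ferritin = seq(5, 30, by = 1))
  expect_true(all(diff(classify_deficiency(grid)$low_ferritin) <= 0))
  grid <- data.frame(tfr = seq(2, 15, by = 0.5))
  expect_true(all(diff(classify_deficiency(grid)$high_tfr) >= 0))
  expect_error(classify_deficiency(data.frame(retinol = -0.1)), "negative")
})

test_that("inflammation adjustment corrects toward the latent prevalence", {
  # no inflammation signal in the biomarker -> adjustment is a no-op
  conc <- rep(10, 100)
  ln_agp <- rnorm(100)
  out <- adjust_inflammation_brinda(conc, ln_agp)
  expect_equal(as.vector(out), conc)
  # below the reference nothing changes even with a slope
  set.seed(1)
  ln_agp <- rnorm(200)
  conc <- exp(2 + 0.5 * ln_agp + rnorm(200, 0, 0.1))
  ref <- quantile(ln_agp, 0.10, names = FALSE)
  out <- adjust_inflammation_brinda(conc, ln_agp, ref_ln_agp = ref)
  expect_equal(out[ln_agp <= ref], conc[ln_agp <= ref])
  expect_true(all(out[ln_agp > ref] < conc[ln_agp > ref]))
  expect_warning(adjust_inflammation_brinda(conc[1:10], ln_agp[1:10]),
                 "fewer than")
  # cohort with built-in AGP distortion of ferritin: adjusted prevalence of
  # low ferritin is closer to the latent prevalence than unadjusted
  cfg <- sim_config(children_per_site = 120, seed = 31,
                    agp_distortion = c(ferritin = 0.6, retinol = 0,
                                       zinc = 0, tfr = 0))
  co <- generate_cohort(cfg, null_truth())
  pp <- preprocess_cohort(co, required = c("mpo", "lmz", "agp"))
  latent_prev <- mean(co$latents$d_low_ferritin)
  pv <- pp$prevalence
  pv <- pv[pv$outcome == "low_ferritin", ]
  w <- table(co$children$site)[pv$site]
  unadj <- weighted.mean(pv$prevalence_unadjusted, w)
  adj <- weighted.mean(pv$prevalence_adjusted, w)
  expect_lt(abs(adj - latent_prev), abs(unadj - latent_prev))
})

test_that("standardization has the closed form and affine invariance", {
  out <- standardize(data.frame(a = c(1, 2, 3)))
  expect_equal(out$x$a, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(out$scale[["a"]], 1) # denominator n - 1
  expect_equal(standardize(data.frame(a = c(1, 2, 3) * 1000 + 7))$x$a,
               out$x$a, tolerance = 1e-12)
  twice <- standardize(out$x)
  expect_equal(twice$x$a, out$x$a, tolerance = 1e-12)
  set.seed(2)
  m <- data.frame(u = rnorm(50, 5, 3), v = runif(50))
  z <- standardize(m)$x
  expect_true(all(abs(colMeans(z)) < 1e-8))
  expect_true(all(abs(vapply(z, sd, numeric(1)) - 1) < 1e-8))
  expect_error(standardize(data.frame(ok = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("complete-case selection drops and logs by variable and site", {
  rows <- data.frame(site = rep(c("A", "B"), each = 5),
                     x = c(NA, rnorm(9)), y = rnorm(10))
  cc <- complete_cases(rows, c("x", "y"))
  expect_equal(nrow(cc$data), 9)
  expect_equal(unname(cc$exclusions$by_variable["x"]), 1)
  expect_equal(unname(cc$exclusions$by_site[["A"]]), 1)
  full <- complete_cases(rows[-1, ], c("x", "y"))
  expect_equal(nrow(full$data), 9)
  expect_equal(full$exclusions$n_dropped, 0)
  rows$x <- NA_real_
  expect_error(complete_cases(rows, "x"), "every row")
  # retained fraction under independent missingness matches expectation
  set.seed(9)
  n <- 4000
  p_each <- 0.1
  d <- data.frame(a = ifelse(runif(n) < p_each, NA, 1),
                  b = ifelse(runif(n) < p_each, NA, 1))
  kept <- nrow(complete_cases(d, c("a", "b"))$data) / n
  p_keep <- (1 - p_each)^2
  expect_lt(abs(kept - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / n))
})

test_that("preprocessing round-trips the generator's latent variables", {
  cfg <- sim_config(children_per_site = 80, seed = 12)
  co <- generate_cohort(cfg, default_truth())
  pp <- preprocess_cohort(co)
  a <- merge(pp$analytic, co$latents, by = "child_id",
             suffixes = c("", ".lat"))
  for (v in c("iron", "zinc", "vit_a", "mpo", "neo", "aat", "lmz", "agp")) {
    expect_gt(cor(a[[v]], a[[paste0(v, ".lat")]]), 0.9)
  }
  # deficiency flags equal the simulated states exactly (no distortion)
  for (o in c("anemia", "low_ferritin", "high_tfr", "low_retinol",
              "low_zinc")) {
    expect_equal(a[[o]], a[[paste0("d_", o)]])
  }
  # standardized columns are exactly centered and scaled
  std <- c("iron", "zinc", "mpo", "lmz", "agp")
  expect_true(all(abs(colMeans(a[, std])) < 1e-8))
  expect_true(all(abs(vapply(a[, std], sd, numeric(1)) - 1) < 1e-8))
})
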