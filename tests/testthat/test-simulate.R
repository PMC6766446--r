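test_that("identical config and seed give byte-identical cohorts", {
  cfg <- sim_config(sites = c("BGD", "BRF"), children_per_site = 10, seed = 42)
  co1 <- generate_cohort(cfg, default_truth())
  co2 <- generate_cohort(cfg, default_truth())
  for (nm in c("children", "recalls", "stool", "lm", "blood", "latents")) {
    expect_identical(co1[[nm]], co2[[nm]])
  }
  co3 <- generate_cohort(sim_config(sites = c("BGD", "BRF"),
                                    children_per_site = 10, seed = 43),
                         default_truth())
  expect_false(identical(co1$blood, co3$blood))
})

test_that("truth_table maps coefficients to odds ratios and counts arcs", {
  tr <- truth_dag(data.frame(parent = c("zinc", "mpo"),
                             child = c("lmz", "anemia"),
                             beta = c(0, log(2))))
  tt <- truth_table(tr)
  expect_equal(nrow(tt), 2)
  expect_true(is.na(tt$or_true[tt$child == "lmz"])) # linear child: no OR
  expect_equal(tt$or_true[tt$child == "anemia"], 2)
  tt0 <- truth_table(truth_dag(data.frame(parent = "lmz", child = "anemia",
                                          beta = 0)))
  expect_equal(tt0$or_true, 1)
  expect_equal(nrow(truth_table(default_truth())),
               nrow(default_truth()$arcs))
})

test_that("truth DAG rejects arcs against the layer order", {
  expect_error(truth_dag(data.frame(parent = "anemia", child = "zinc",
                                    beta = 0.1)), "layer order")
  expect_error(truth_dag(data.frame(parent = "mpo", child = "lmz",
                                    beta = 0.1)), "layer order")
  expect_error(truth_dag(data.frame(parent = "nonsense", child = "lmz",
                                    beta = 0.1)), "unknown")
  expect_error(generate_cohort(sim_config(sites = c("XX", "BRF"))),
               "unknown site")
})

test_that("null truth yields mutually uncorrelated preprocessed variables", {
  cfg <- sim_config(sites = c("BGD", "BRF"), children_per_site = 60,
                    seed = 5,
                    missing_rates = list(recall = 0, stool = 0, lm = 0,
                                         blood = 0))
  pp <- preprocess_cohort(generate_cohort(cfg, null_truth()))
  a <- pp$analytic
  # within-site correlations of variables linked only through the (absent)
  # truth arcs should be sampling noise
  for (pair in list(c("zinc", "lmz"), c("vit_a", "mpo"), c("agp", "aat"))) {
    r <- mean(sapply(split(a, a$site), function(g) {
      cor(g[[pair[1]]], g[[pair[2]]])
    }))
    expect_lt(abs(r), 0.25)
  }
})

test_that("a single planted arc is recovered, with latent OLS as oracle", {
  beta_true <- -0.14
  cfg <- sim_config(children_per_site = 185, seed = 9, noise = low_noise())
  co <- generate_cohort(cfg, zinc_lmz_truth(beta_true))
  # oracle: ordinary least squares on the generated latent values
  lat <- co$latents
  oracle <- unname(coef(lm(lmz ~ zinc + site, data = lat))["zinc"])
  expect_lt(abs(oracle - beta_true), 0.06)
  # estimate from the observable streams after preprocessing
  pp <- preprocess_cohort(co)
  est <- unname(coef(lm(lmz ~ zinc + site, data = pp$analytic))["zinc"])
  expect_lt(abs(est - oracle), 0.06)
  expect_lt(abs(est - beta_true), 0.12) # ~3 within-site-design SEs
})

test_that("site calibration, prevalence targets, and missingness hold", {
  cfg <- sim_config(children_per_site = 150, seed = 21)
  co <- generate_cohort(cfg, null_truth())
  pp <- preprocess_cohort(co)

  # site-mean log fecal biomarkers within +/- 0.3 of the configured targets
  fec <- merge(pp$summaries$fecal, co$children[, c("child_id", "site")])
  calib <- cfg$calibration
  for (v in c("mpo", "neo", "aat")) {
    mns <- tapply(fec[[v]], fec$site, mean)
    target <- calib[calib$variable == paste0("ln_", v), ]
    expect_true(all(abs(mns[target$site] - target$mean) < 0.3),
                label = paste("site means of ln", v))
  }

  # with all arcs absent, site prevalences track the configured targets
  bl <- pp$summaries$blood
  for (o in c("anemia", "low_ferritin", "low_retinol")) {
    obs <- tapply(bl[[o]], bl$site, mean, na.rm = TRUE)
    n_site <- tapply(!is.na(bl[[o]]), bl$site, sum)
    tgt <- cfg$prevalence
    tgt <- tgt$prevalence[tgt$outcome == o][match(names(obs),
                                                  tgt$site[tgt$outcome == o])]
    se <- sqrt(tgt * (1 - tgt) / n_site)
    expect_true(all(abs(obs - tgt) < 3 * se), label = paste("prevalence", o))
  }

  # per-stream missingness within 3 SE of the configured rates
  n_children <- nrow(co$children)
  n_expected <- n_children * length(cfg$months)
  p_miss <- cfg$missing_rates$recall
  se <- sqrt(p_miss * (1 - p_miss) / n_expected)
  expect_lt(abs((1 - nrow(co$recalls) / n_expected) - p_miss), 3 * se)
  n_expected <- n_children * length(cfg$stool_ages)
  p_miss <- cfg$missing_rates$stool
  se <- sqrt(p_miss * (1 - p_miss) / n_expected)
  expect_lt(abs((1 - nrow(co$stool) / n_expected) - p_miss), 3 * se)
  p_miss <- cfg$missing_rates$blood
  se <- sqrt(p_miss * (1 - p_miss) / (6 * n_children))
  expect_lt(abs(mean(is.na(co$blood[, -1])) - p_miss), 3 * se)
})

test_that("cohort CSV round trip preserves the streams", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(sites = c("BGD", "BRF"), children_per_site = 8, seed = 3)
  co <- generate_cohort(cfg, default_truth())
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("children.csv", "recalls.csv",
                                               "stool.csv", "lm.csv",
                                               "blood.csv", "truth.json")))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$children), nrow(co$children))
  expect_equal(back$blood$hemoglobin, co$blood$hemoglobin, tolerance = 1e-8)
})
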