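test_that("verdict rules follow the total-vs-direct comparison", {
  # pattern of a fully mediated pair: strong total, null direct
  univ <- data.frame(exposure = "iron", outcome = "low_retinol",
                     estimate = log(0.71), lo = log(0.57), hi = log(0.88))
  net <- data.frame(child = "low_retinol", term = "iron", role = "arc",
                    family = "logistic", mean = log(1.08), sd = 0.15,
                    lo = log(0.80), hi = log(1.45), or = 1.08,
                    or_lo = 0.80, or_hi = 1.45, rhat = 1, ess = 1000,
                    converged = TRUE)
  out <- total_vs_direct(univ, net)
  expect_equal(out$verdict, "full")
  # total == direct exactly: proportion attenuated 0, verdict none
  net2 <- net
  net2$mean <- log(0.71); net2$lo <- log(0.57); net2$hi <- log(0.88)
  out2 <- total_vs_direct(univ, net2)
  expect_equal(out2$verdict, "none")
  expect_equal(out2$proportion_attenuated, 0)
  # both significant, attenuated direct: partial
  net3 <- net
  net3$mean <- log(0.85); net3$lo <- log(0.75); net3$hi <- log(0.96)
  expect_equal(total_vs_direct(univ, net3)$verdict, "partial")
  # pairs absent from one layer are skipped with a message
  univ2 <- rbind(univ, data.frame(exposure = "vit_c", outcome = "low_retinol",
                                  estimate = 0, lo = -0.1, hi = 0.1))
  expect_message(out3 <- total_vs_direct(univ2, net), "skipped")
  expect_equal(nrow(out3), 1)
})

test_that("indirect products recover planted path effects", {
  # both legs 0.2: indirect product ~ 0.04; zero first leg: CrI covers 0
  d <- linear_chain_data(n = 4000, b_xm = 0.2, b_my = 0.2, b_xy = 0,
                         seed = 20)
  fit <- fit_network(d, chain_spec(), quick_mcmc(seed = 7))
  ind <- indirect_effects(fit, mediators = "m")
  expect_lt(abs(ind$paths$indirect - 0.04), 0.02)
  expect_equal(ind$totals$indirect_total, ind$paths$indirect)
  d0 <- linear_chain_data(n = 2000, b_xm = 0, b_my = 0.4, b_xy = 0.2,
                          seed = 21)
  fit0 <- fit_network(d0, chain_spec(), quick_mcmc(seed = 8))
  ind0 <- indirect_effects(fit0, mediators = "m")
  expect_true(ind0$paths$lo < 0 && ind0$paths$hi > 0)
})

test_that("path-tracing identity holds on an all-linear chain", {
  d <- linear_chain_data(n = 2500, seed = 22)
  dec <- path_decomposition(d, chain_spec(), "x", "y",
                            mcmc = quick_mcmc(seed = 9), mediators = "m")
  # total ~ b_xy + b_xm * b_my = 0.3 + 0.2
  expect_equal(dec$total, 0.5, tolerance = 0.08)
  expect_lt(abs(dec$gap), 0.03)
})

test_that("mediation is invariant to the sign convention of the mediator", {
  d <- linear_chain_data(n = 2500, b_xm = 0.4, b_my = 0.3, b_xy = 0.1,
                         seed = 23)
  flipped <- d
  flipped$m <- -flipped$m
  mc <- quick_mcmc(seed = 10)
  ind <- indirect_effects(fit_network(d, chain_spec(), mc), mediators = "m")
  ind_f <- indirect_effects(fit_network(flipped, chain_spec(), mc),
                            mediators = "m")
  expect_equal(ind$paths$indirect, ind_f$paths$indirect, tolerance = 0.02)
})

test_that("fever covariates independent of the system leave arcs unchanged", {
  cfg <- sim_config(sites = c("BGD", "INV", "BRF"), children_per_site = 160,
                    seed = 41, fever_agp_coef = 0)
  co <- generate_cohort(cfg, zinc_lmz_truth(-0.3))
  pp <- preprocess_cohort(co)
  spec <- mediation_spec()
  out <- sensitivity_fever(pp$analytic, spec,
                           quick_mcmc(seed = 11, n_iter = 2000,
                                      n_burnin = 1000))
  expect_lt(out$max_shift, 0.1)
  expect_true(all(c("mean_base", "mean_fever", "shift") %in%
                    names(out$comparison)))
  # degenerate fever column is dropped with a warning
  a2 <- pp$analytic
  a2$fever_prior7 <- 0
  expect_warning(sensitivity_fever(a2, spec, quick_mcmc(seed = 12)),
                 "degenerate")
  expect_error(sensitivity_fever(pp$analytic[, setdiff(names(pp$analytic),
                                                       "fever_frac")],
                                 spec, quick_mcmc()),
               "fever column")
})
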