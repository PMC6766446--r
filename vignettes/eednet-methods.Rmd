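---
title: "Methods: diet, gut function, and micronutrient status in a multi-site cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet, gut function, and micronutrient status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Children growing up with chronic enteropathogen exposure commonly develop
environmental enteric dysfunction (EED): a subclinical state of intestinal
inflammation, increased permeability, and reduced absorptive surface. EED is
a leading candidate explanation for why micronutrient deficiencies persist
in low-resource settings even where complementary-food quality improves.
`eednet` implements an analysis pipeline for the question: *do nutrient
densities of complementary foods relate to micronutrient status directly, or
through the gut-function biomarkers of EED?*

The data model is a 7-site longitudinal infant cohort observed from 9 to 15
months: monthly quantitative 24-h dietary recalls (energy and nutrient
intakes from non-breast-milk foods), monthly non-diarrheal stool assays of
myeloperoxidase (MPO, neutrophil activation), neopterin (NEO, T-cell
activity) and alpha-1-antitrypsin (AAT, protein loss/permeability),
dual-sugar (lactulose:mannitol) permeability tests at 9 and 15 months, and a
15-month blood panel (hemoglobin, retinol, ferritin, transferrin receptor,
zinc, and alpha-1-acid glycoprotein (AGP) as the systemic-inflammation
marker).

## Pipeline

1. **Preprocessing** (`preprocess_cohort()`): nutrient densities (intake per
   1000 kcal) are square-root transformed *per recall* and then averaged per
   child; fecal biomarkers are log-transformed per sample and then averaged;
   the dual-sugar results are expressed as age- and sex-referenced z-scores
   (%Lac-Z, %Man-Z, and LMZ); hemoglobin is altitude-adjusted; deficiency
   flags apply fixed clinical cutoffs; children missing any required model
   variable are excluded (complete-case analysis, no imputation); the
   continuous model variables are standardized to mean 0, SD 1 over the
   analytic sample.
2. **Univariate screens** (`univariate_screen()`): one exposure at a time,
   generalized linear mixed models with site as a random intercept.
   Deficiency outcomes give odds ratios per 1 SD, adjusted for ln AGP;
   continuous biomarker outcomes give mean effects per 1 SD (not
   AGP-adjusted, matching the screening-table convention of the analysis
   this package emulates).
3. **Bayesian network** (`fit_network()`): the joint model over the fixed
   a-priori DAG factorizes into conditionally independent generalized linear
   regressions, one per node, each with site dummy variables.
4. **Mediation** (`total_vs_direct()`, `indirect_effects()`): the total
   (univariate) and direct (network) diet effects are compared, and indirect
   effects through each EED biomarker are computed as products of
   coefficients over the joint posterior.

## The network model

The DAG is fixed a priori in layers: diet densities (exposures, no parents)
point at the EED biomarkers (mean ln MPO, ln NEO, ln AAT, and LMZ) and at
ln AGP; diet, EED, and AGP all point at the binary deficiency outcomes (low
ferritin, high TfR, low retinol, low zinc); and the four deficiency outcomes
additionally point at anemia. Folate and vitamin C are excluded from the
default diet set (they were screened out ahead of the multivariable model in
the emulated analysis; `build_network(diet_vars = ...)` overrides this).
Structure learning is out of scope: only coefficients are estimated.

For a linear node $j$ with parent set $\mathrm{pa}(j)$ and site $s(i)$:

$$y_{ij} = \alpha_{j,s(i)} + \sum_{k \in \mathrm{pa}(j)} \beta_{kj}\, x_{ik}
  + \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_j^2)$$

and for a binary node, $\mathrm{logit}\,P(y_{ij} = 1)$ equals the same
linear predictor. Because all variables are standardized, $\beta_{kj}$ is a
mean effect (or log odds) per 1 SD, which is also the scale of the
ground-truth coefficients in the simulator.

**Priors.** Coefficients $\beta \sim N(0, 10^2)$ on the standardized scale;
linear-node residual SDs $\sigma \sim$ half-Cauchy(1). The emulated analysis
reports no priors, so these are the package's own weakly informative
choices; at the analytic sample sizes involved (hundreds to thousands) the
likelihood dominates.

**Sampling.** Linear nodes use a conjugate Gibbs sampler; the half-Cauchy
prior enters through its inverse-gamma mixture representation, so every
conditional is closed-form. Logistic nodes use Gibbs with Polya-Gamma
augmentation (exact conditional conjugacy; the PG(1, z) variates are drawn
with a Devroye-type exact sampler in compiled code). A random-walk
Metropolis fallback (`mcmc_config(method = "metropolis")`, Laplace-scaled
joint proposals) is retained and tested against the same oracles. Defaults:
4 chains x 5000 iterations, 2500 burn-in, thin 1; chains are initialized
overdispersed; convergence gates are split-Rhat <= 1.01 and ESS >= 400.
An arc is *significant* when its equal-tailed 95% credibility interval
excludes the null; no multiplicity adjustment is applied.

Node samplers are seeded from the node *name*, so fitting a node alone or
inside the full network yields identical draws for the same master seed —
the sampling-level expression of the conditional-independence
factorization.

## Preprocessing details and numerical choices

- **Transform order is fixed**: square root / natural log per observation,
  then the within-child mean, then standardization (SD with denominator
  n-1). The non-commutativity is asserted by test (densities 9 and 25 give
  a mean sqrt-density of 4, not sqrt(17)).
- **Deficiency cutoffs** (all strict, as printed in the field's
  definitions): hemoglobin < 11.0 g/dL (altitude-adjusted), retinol < 0.70
  umol/L, zinc < 9.9 umol/L, ferritin < 12 ug/L, TfR > 8.3 mg/L, AGP > 1
  g/L.
- **Altitude adjustment** subtracts $\max(0,\, -0.032a + 0.022a^2)$ g/dL
  with $a$ = altitude in thousands of feet, applied above 3000 ft — the
  standard polynomial behind hemoglobin altitude corrections.
- **Dual-sugar reference**: rather than an external normative standard, the
  reference model (ln % recovery on age and sex, for each sugar and for
  their ratio) is fitted internally on the designated reference site and
  applied to all children; the reference stratum therefore z-scores itself
  to mean 0, SD 1. LMZ is defined as the z-score of ln(L:M ratio). An
  alternative definition — the difference of the two sugar z-scores — is
  monotonically related but not identical; the ratio form was chosen
  because the ratio is the quantity with an established clinical
  interpretation.
- **Inflammation adjustment** (for prevalence reporting only, never for the
  model variables): a single-covariate regression correction on the log
  scale, $\tilde c = \exp(\ln c - \hat\beta\,(\ln AGP - \ln AGP_{ref}))$,
  with the reference at the lowest decile of ln AGP and adjustment applied
  only above it. CRP is not part of the data model, so the correction uses
  ln AGP alone; at least 50 observations are required to estimate the
  slope.
- **Degenerate inputs**: recalls with nonpositive energy and stool assays
  with nonpositive concentrations are rejected with a warning; a missing
  analyte yields an undefined (NA) flag rather than "not deficient";
  constant columns make standardization fail loudly with the column name.

## The synthetic cohort generator

No individual-level data ship with the package; every analysis is
exercisable on cohorts from `generate_cohort()`, which emulates the
*structure* of the 7-site study with a known ground truth:

- **Latent-first design.** Each child draws pooled-standardized latent
  values for the transformed diet densities (exchangeable within-child
  correlation 0.4), the EED biomarkers, LMZ, and ln AGP — exactly the scale
  the estimators report. Ground-truth arcs act on this scale; binary
  deficiency states are Bernoulli draws from a logit model whose per-site
  intercepts hit calibrated prevalence targets. Observables are then
  back-transformed (squaring densities, exponentiating biomarkers,
  re-expressing LMZ through synthetic sugar recoveries) with site shifts
  and within-child month-to-month noise, so that preprocessing approximately
  recovers the latents.
- **Calibration.** Site-level means and SDs of the transformed observables,
  per-site deficiency prevalence targets, altitudes, and sample sizes live
  in `inst/extdata/site_calibration.csv`, `site_prevalence.csv`, and
  `site_info.csv`, transcribed from the published site-stratified summary
  tables of a 7-site infant cohort. Blood concentrations are generated
  conditionally on the binary deficiency state (lognormal spread away from
  the cutoff), because the published concentration summaries for the blood
  panel are not internally consistent in their printed units.
- **Within-child noise.** Month-to-month variance components are not
  published for the emulated cohort. Defaults — SD 0.6 on the log scale per
  stool sample, 0.45 z-units per dual-sugar test, 0.25 pooled-SD units per
  recall — were chosen once as realistic magnitudes (they reproduce
  child-mean reliabilities around 0.85-0.99) and are stated here because
  they are a package choice, not a reported quantity.
- **Reproducibility.** One master seed; every child draws from a substream
  seeded by an avalanche-hashed (seed, counter) pair, so cohorts are
  byte-identical across runs and independent of iteration order. (A linear
  substream derivation was observed to induce cross-stream correlations in
  the underlying generator and is deliberately avoided.)
- **Not simulated**: enteropathogen detections, breast-milk intake and
  composition, anthropometry, diarrheal episodes, assay chemistry.

## Simulation studies and what they show

`coverage_study()` and `mediation_study()` run the full pipeline
(generate, preprocess, fit) on every replicate:

- **Coverage**: a study-shaped truth plants arcs at |beta| = 0.1 and 0.2
  (linear) and |log OR| = ln 1.25 (logistic) among a majority of null arcs;
  over replicates of 7 sites x 200 children the 95% CrIs should cover the
  generating values 93-97% per effect-size class, and null arcs should be
  flagged significant about 5% of the time.
- **Mediation**: a fully mediated truth (zinc density -> LMZ -> low
  retinol, coefficients -0.6 and 0.75, no direct arc) should yield the
  "full" verdict in at least 80% of replicates — the planted path is sized
  so the marginal (total) association is about three standard errors at
  n = 1400 — while a null truth should yield it rarely (<= 7%).

These studies run at 50 replicates with 2 chains x 1200 iterations per
node, analytic n = 1400 (no missingness), and *low* measurement noise
(recall 0.1, stool 0.25, dual-sugar 0.2), so that per-child means identify
the latent scale on which the truth is defined; with realistic noise the
per-child means attenuate arc estimates by a few percent (an inherent
feature of error-in-variables regression, not of the sampler), which the
round-trip checks quantify instead. Replicate counts and chain lengths are
the package's own desk-scale choices.

**What passing does not show about real data.** The generator draws from
the estimator's own model family (linearity on the transformed scale,
homogeneous arc effects across sites, logistic outcomes, conditionally
independent noise). Real cohorts can violate any of these — nonlinear
dose-response, site-by-exposure interactions, unmeasured confounding of the
diet-EED-status pathway, informative missingness — and nothing in the suite
tests robustness to them. The pipeline reports associations under a fixed
a-priori DAG, as the emulated analysis does; it makes no causal
identification claims.

## Known limitations

- Odds ratios are non-collapsible: total = direct + sum(indirect) holds
  exactly only for all-linear chains, and the decomposition identity is
  asserted only there. For logistic outcomes the verdict rule and the
  product-of-coefficients estimator are reported as separate, clearly
  labeled summaries.
- The mediation estimand is the package's formalization; the qualitative
  appears/disappears comparison alone is not a testable quantity.
- Only the four deficiency -> anemia outcome-to-outcome arcs are modeled;
  other outcome interdependencies are absorbed into residual noise.
- Blood concentrations are simulated conditionally on the binary deficiency
  states, so concentration-level correlations among the iron markers
  (ferritin, TfR, hemoglobin) are far weaker than in real cohorts, where
  they are biologically coupled; the within-site Spearman summaries are
  therefore informative about the code path, not about realistic marker
  correlation structure.
- Measurement-error and latent-variable extensions (e.g. treating the
  biomarkers as noisy indicators of a latent EED construct) are out of
  scope.
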