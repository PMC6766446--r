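# eednet

Does the gut mediate the link between diet quality and micronutrient
deficiency in young children? `eednet` is an R package for analysing
multi-site longitudinal infant cohorts in which the nutrient density of
complementary foods (9–15 months), fecal biomarkers of environmental
enteric dysfunction (EED: myeloperoxidase, neopterin, alpha-1-antitrypsin),
dual-sugar permeability tests (lactulose:mannitol z-scores), systemic
inflammation (alpha-1-acid glycoprotein, AGP) and a 15-month blood panel
are observed together. It is written for biostatisticians and nutrition
epidemiologists who want the full chain — preprocessing, univariate mixed
screens, a Bayesian network of generalized linear regressions, and a
mediation comparison — as tested, reusable functions, exercisable end to
end on a bundled synthetic-cohort generator with known ground truth.

## The model at its core

Over a fixed, layered DAG (diet → {MPO, NEO, AAT, LMZ, AGP} → {low
ferritin, high TfR, low retinol, low zinc} → anemia), the joint
distribution factorizes into conditionally independent GLMs, one per node
*j*:

```
y_ij      = alpha_{j,s(i)} + sum_k beta_kj x_ik + eps_ij      (linear nodes)
logit P(y_ij = 1) = alpha_{j,s(i)} + sum_k beta_kj x_ik       (binary nodes)
```

with site dummies `alpha_{j,s}` per node, all variables standardized so
`beta_kj` is a mean effect (or log OR) per 1 SD. Coefficients get
`N(0, 10^2)` priors and linear residual SDs get half-Cauchy(1); linear
nodes are sampled by conjugate Gibbs and binary nodes by Gibbs with
Polya-Gamma augmentation (compiled, exact). An arc is *significant* when
its equal-tailed 95% credibility interval excludes the null. Mediation is
read off by comparing each diet exposure's **total** effect (univariate
mixed model: `outcome ~ exposure + ln AGP + (1 | site)`) with its
**direct** effect (the network arc, conditioned on the EED layer), plus
product-of-coefficients indirect effects computed draw-by-draw from the
joint posterior.

## Worked example

Simulate a calibrated 7-site cohort from the default ground truth,
preprocess it, and fit the network:

```r
library(eednet)

cohort   <- generate_cohort(sim_config(seed = 1), default_truth())
prep     <- preprocess_cohort(cohort)
nrow(prep$analytic)
#> [1] 927

fit <- fit_network(prep$analytic, build_network(),
                   mcmc_config(n_chains = 2, n_iter = 2000,
                               n_burnin = 1000, seed = 1))
sig <- significant_arcs(fit)
head(sig[order(-sig$magnitude), c("parent", "child", "mean", "lo", "hi", "or")], 5)
#>          parent       child      mean        lo        hi       or
#> 25 low_ferritin      anemia 1.3317257 1.0231143 1.6579674 3.787574
#> 26     high_tfr      anemia 0.8545825 0.5182641 1.1877152 2.350393
#> 27  low_retinol      anemia 0.6955643 0.3400828 1.0521623 2.004840
#> 22        vit_a      anemia 0.5619167 0.2653838 0.8547584 1.754031
#> 20          agp low_retinol 0.5034566 0.3322850 0.6721205 1.654430
```

Each row is an arc: `mean` is the posterior mean per 1 SD on the linear or
log-odds scale (`or` exponentiates it for binary children), and `lo`/`hi`
are the 95% credibility bounds. The strongest signals are the planted
deficiency→anemia arcs (generating ORs 2.79 and 2.26), the vitamin-A→anemia
arc (generating OR 1.52) and the inflammation effect on low retinol
(generating OR 1.58) — all with the expected signs at this single-cohort
sample size. The mediation layer then contrasts totals with directs:

```r
screen <- univariate_screen(prep$analytic)
med    <- total_vs_direct(screen$binary, fit)
table(med$verdict)
#>
#>    full    none partial
#>       1      53       1
```

A `"full"` verdict means the univariate CI excluded the null but the
EED-adjusted network CrI did not — the pattern expected when the gut
biomarker layer carries the association.

The same stages are available as numbered drivers
(`analysis/01_simulate.R` … `analysis/05_mediation.R`, writing their
tables under `results/`) and as a single orchestrated call,
`run_pipeline(run_config(...))`, which also writes a manifest with file
hashes, the seed, and convergence status.

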