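#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic multi-site cohort.
#
# Generates a 7-site cohort (calibrated site magnitudes, ~1300 children)
# from the default ground-truth DAG and writes the raw longitudinal streams
# under results/cohort/. Downstream stages read only those CSVs.

suppressPackageStartupMessages(library(eednet))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- sim_config(seed = seed)
truth <- default_truth()
cohort <- generate_cohort(cfg, truth)
write_cohort(cohort, "results/cohort")

cat("simulated", nrow(cohort$children), "children across",
    nrow(cfg$sites), "sites (seed", seed, ")\n")
cat("streams: recalls", nrow(cohort$recalls), "| stool", nrow(cohort$stool),
    "| dual-sugar tests", nrow(cohort$lm), "| blood panels",
    nrow(cohort$blood), "\n")
tt <- truth_table(truth)
cat("ground truth:", nrow(tt), "arcs;",
    sum(tt$family == "logistic"), "on the log-odds scale\n")
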