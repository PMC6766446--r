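# Pipeline orchestration and publication-shaped outputs: one config drives
# simulate -> preprocess -> univariate -> network -> mediation, with a run
# manifest recording seeds, file hashes, and convergence status.

#' Configuration for a full pipeline run
#'
#' @param out_dir output directory.
#' @param seed master seed for the run (simulation and MCMC).
#' @param simulate generate a synthetic cohort (default); otherwise
#'   `input_dir` must point at cohort CSVs in the [write_cohort()] layout.
#' @param input_dir directory of input CSVs when `simulate = FALSE`.
#' @param sim an [sim_config()] (its seed is overridden by `seed`).
#' @param truth ground-truth DAG used when simulating.
#' @param diet_vars diet variables retained in the network.
#' @param mcmc an [mcmc_config()] (seed overridden by `seed`).
#' @param run_fever also run the fever-covariate sensitivity refit.
#' @return an `eed_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE, input_dir = NULL,
                       sim = sim_config(), truth = default_truth(),
                       diet_vars = c("iron", "zinc", "calcium", "vit_a",
                                     "vit_b6", "vit_b12", "protein"),
                       mcmc = mcmc_config(), run_fever = FALSE) {
  if (!simulate && is.null(input_dir)) {
    stop("simulation disabled but no input_dir given")
  }
  if (!simulate && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  sim$seed <- as.integer(seed)
  mcmc$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input_dir = input_dir, sim = sim,
                 truth = truth, diet_vars = diet_vars, mcmc = mcmc,
                 run_fever = run_fever),
            class = "eed_run_config")
}

#' Run the full pipeline
#'
#' Executes every stage and writes its outputs under `config$out_dir`:
#' cohort CSVs (when simulating), `analytic.csv`, `prevalence.csv`,
#' `exclusions.json`, the univariate screen tables, the network arc table,
#' the significant-arc graph (DOT and GraphML), the mediation table, and a
#' `manifest.json` tying every file to its md5 hash, the seed, and the
#' convergence status.
#'
#' @param config an [run_config()].
#' @return the manifest (list), invisibly; stage results in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "eed_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (config$simulate) {
      co <- generate_cohort(config$sim, config$truth)
      write_cohort(co, file.path(out, "cohort"))
      co
    } else {
      read_cohort(config$input_dir)
    }
  })

  prep <- stage("preprocess", preprocess_cohort(cohort))
  write.csv(prep$analytic, file.path(out, "analytic.csv"), row.names = FALSE)
  # prevalence reporting uses inflammation-ADJUSTED values; the network
  # consumes unadjusted values (provenance tagged in the table itself)
  prevalence <- prep$prevalence
  prevalence$provenance <- "inflammation-adjusted (reporting only)"
  write.csv(prevalence, file.path(out, "prevalence.csv"), row.names = FALSE)
  jsonlite::write_json(prep$exclusions, file.path(out, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  screen <- stage("univariate", univariate_screen(prep$analytic))
  b <- screen$binary
  b$star <- ifelse(b$significant, "*", "")
  b$provenance <- "unadjusted biochemical values"
  write.csv(b, file.path(out, "table3_analogue.csv"), row.names = FALSE)
  cn <- screen$continuous
  cn$star <- ifelse(cn$significant, "*", "")
  write.csv(cn, file.path(out, "table4_analogue.csv"), row.names = FALSE)

  spec <- build_network(diet_vars = config$diet_vars)
  netfit <- stage("network", fit_network(prep$analytic, spec, config$mcmc))
  arc_table <- netfit$summary[netfit$summary$role == "arc", ]
  arc_table$provenance <- "unadjusted biochemical values"
  write.csv(arc_table, file.path(out, "network_arcs.csv"), row.names = FALSE)
  sig <- significant_arcs(netfit)
  write_dot(sig, spec, file.path(out, "significant_arcs.dot"))
  write_graphml(sig, spec, file.path(out, "significant_arcs.graphml"))

  med <- stage("mediation", {
    m <- total_vs_direct(screen$binary, netfit)
    ind <- indirect_effects(netfit)
    list(table = m, indirect = ind)
  })
  mt <- med$table
  mt$estimand <- "qualitative verdict + product-of-coefficients (package-defined)"
  write.csv(mt, file.path(out, "mediation_table.csv"), row.names = FALSE)
  if (!is.null(med$indirect$paths)) {
    write.csv(med$indirect$paths, file.path(out, "indirect_paths.csv"),
              row.names = FALSE)
  }

  fever <- NULL
  if (config$run_fever) {
    fever <- stage("sensitivity_fever",
                   sensitivity_fever(prep$analytic, spec, config$mcmc))
    write.csv(fever$comparison, file.path(out, "sensitivity_comparison.csv"),
              row.names = FALSE)
  }

  desc <- render_tables(cohort, prep)
  write.csv(desc$table1, file.path(out, "table1_analogue.csv"),
            row.names = FALSE)
  write.csv(desc$table2, file.path(out, "table2_analogue.csv"),
            row.names = FALSE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("eednet")),
    simulated = config$simulate,
    stages = c("simulate", "preprocess", "univariate", "network",
               "mediation", if (config$run_fever) "sensitivity_fever"),
    n_analytic = nrow(prep$analytic),
    converged = all(netfit$summary$converged),
    files = data.frame(path = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results <- list(cohort = cohort, preprocessed = prep, screen = screen,
                  network = netfit, mediation = med, fever = fever)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Site-stratified descriptive tables
#'
#' Builds analogues of the study's descriptive tables: biomarkers of gut
#' function, micronutrient status and inflammation by site (mean +/- SD of
#' the per-child summaries), and energy/macronutrient/nutrient-density
#' intakes by site.
#'
#' @param cohort an `eed_cohort`.
#' @param prep result of [preprocess_cohort()].
#' @return list `table1`, `table2` (data frames, one row per site).
#' @export
render_tables <- function(cohort, prep) {
  ch <- cohort$children[, c("child_id", "site")]
  msd <- function(df, vars) {
    d <- merge(df, ch, by = "child_id")
    do.call(rbind, lapply(split(d, d$site), function(g) {
      row <- data.frame(site = g$site[1])
      for (v in vars) {
        row[[paste0(v, "_mean")]] <- mean(g[[v]], na.rm = TRUE)
        row[[paste0(v, "_sd")]] <- sd(g[[v]], na.rm = TRUE)
      }
      row
    }))
  }
  s <- prep$summaries
  t1 <- Reduce(function(a, b) merge(a, b, by = "site"), list(
    msd(s$lmz, c("lacz", "manz", "lmz")),
    msd(s$fecal, c("mpo", "neo", "aat")),
    msd(s$blood[, c("child_id", "hb_adj", "retinol", "ferritin", "tfr",
                    "zinc", "agp")],
        c("hb_adj", "retinol", "ferritin", "tfr", "zinc", "agp"))))
  energy <- aggregate(cohort$recalls$energy_kcal,
                      list(child_id = cohort$recalls$child_id), mean)
  names(energy)[2] <- "energy_kcal"
  t2 <- Reduce(function(a, b) merge(a, b, by = "site"), list(
    msd(energy, "energy_kcal"),
    msd(s$diet, c("carb_pcte", "protein_pcte", "fat_pcte", DIET_VARS))))
  rownames(t1) <- rownames(t2) <- NULL
  list(table1 = t1, table2 = t2)
}

#' Write a significant-arc graph in DOT format
#'
#' Positive arcs red, negative blue; width proportional to magnitude; solid
#' lines for linear associations, dashed for log-odds.
#'
#' @param arcs output of [significant_arcs()].
#' @param spec the `eed_network` (for the node list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(arcs, spec, path) {
  lines <- c("digraph eednet {", "  rankdir=LR;")
  for (n in spec$nodes$name) {
    lines <- c(lines, sprintf("  \"%s\";", n))
  }
  if (nrow(arcs)) {
    for (k in seq_len(nrow(arcs))) {
      a <- arcs[k, ]
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [color=%s, penwidth=%.2f, style=%s];",
        a$parent, a$child, if (a$sign > 0) "red" else "blue",
        0.5 + 4 * a$magnitude,
        if (a$scale == "log-odds") "dashed" else "solid"))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a significant-arc graph in GraphML format
#'
#' @inheritParams write_dot
#' @return `path`, invisibly.
#' @export
write_graphml <- function(arcs, spec, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="int"/>',
    '  <key id="scale" for="edge" attr.name="scale" attr.type="string"/>',
    '  <graph id="eednet" edgedefault="directed">')
  for (n in spec$nodes$name) {
    lines <- c(lines, sprintf('    <node id="%s"/>', esc(n)))
  }
  if (nrow(arcs)) {
    for (k in seq_len(nrow(arcs))) {
      a <- arcs[k, ]
      lines <- c(lines, sprintf(
        paste0('    <edge source="%s" target="%s">',
               '<data key="weight">%.6f</data>',
               '<data key="sign">%d</data>',
               '<data key="scale">%s</data></edge>'),
        esc(a$parent), esc(a$child), a$magnitude, a$sign, a$scale))
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
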