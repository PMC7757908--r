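#!/usr/bin/env Rscript
## Generate the synthetic half-sib progeny trial used throughout the
## analysis: 73 half-sib families, randomized complete blocks with 2
## replications and 5 plants per plot (730 individuals, 146 plots), six
## annual harvests 2010-2015. Random family, plot and permanent-environment
## trajectories follow degree-1 Legendre regressions whose implied variances
## rise over harvests; residual variances are heterogeneous per harvest.

suppressPackageStartupMessages(library(rrtraj))

seed <- 2026
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_trial(cfg)

write_phenotypes(sim$records, "results/phenotypes.csv")
write_truth_manifest(sim$truth, "results/truth.json")

tl <- sim$truth$timeline
cat("simulated trial written to results/phenotypes.csv\n")
cat(sprintf("  %d records: %d families, %d individuals, %d plots, %d harvests\n",
            nrow(sim$records), length(unique(sim$records$family_id)),
            length(unique(sim$records$individual_id)),
            length(unique(sim$records$plot_id)), length(tl$years)))
cat("  generating per-harvest genetic variance:",
    paste(sprintf("%.4f", variance_trajectory(
      cfg$K_g, legendre_matrix(tl, nrow(cfg$K_g) - 1L))), collapse = " "),
    "\n")
cat("  truth manifest: results/truth.json (seed", seed, ")\n")
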