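#!/usr/bin/env Rscript
## Per-harvest genetic parameters of the selected random regression model:
## variance components via the covariance function, heritability, mean
## selective accuracy, and genetic correlations between pairs of harvests.
## Reads results/phenotypes.csv and results/model_comparison.csv (runs
## 01/02 first if you have not); writes results/variance_components.csv and
## results/genetic_correlations.csv and caches the fit for 04.

suppressPackageStartupMessages(library(rrtraj))

records <- read_phenotypes("results/phenotypes.csv")
sel <- local({
  cmp <- read.csv("results/model_comparison.csv")
  cmp[cmp$selected, ][1, ]
})
cat(sprintf("refitting selected model: degrees g/s/p = %d/%d/%d, %s residual\n",
            sel$degree_genetic, sel$degree_plot, sel$degree_perm,
            sel$residual))
cfg <- rr_config(sel$degree_genetic, sel$degree_plot, sel$degree_perm,
                 residual = sel$residual)
fit <- fit_reml(build_design(records, cfg))
cat(sprintf("  logL = %.4f after %d iterations (converged: %s)\n",
            fit$loglik, fit$iterations, fit$converged))
saveRDS(fit, "results/selected_fit.rds")

tab <- summarize_fit(fit)
write.csv(as.data.frame(tab), "results/variance_components.csv",
          row.names = FALSE, quote = FALSE)
cat("\nper-harvest variance components and genetic parameters:\n")
print(data.frame(harvest = tab$harvest,
                 round(as.data.frame(tab[, 2:6]), 4),
                 h2 = round(tab$h2, 2), accuracy = round(tab$accuracy, 2),
                 mean = round(tab$mean, 3)), row.names = FALSE)

tl <- fit$bundle$timeline
Phi <- legendre_matrix(tl, cfg$degree_genetic)
C <- genetic_correlations(fit$covs$genetic, Phi, labels = tl$years)
write.csv(data.frame(harvest = rownames(C), C, check.names = FALSE),
          "results/genetic_correlations.csv", row.names = FALSE,
          quote = FALSE)
cat("\ngenetic correlations between pairs of harvests:\n")
print(round(C, 2))
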