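#!/usr/bin/env Rscript
## Genetic trajectories of the 73 families over scaled harvest time,
## eigenfunctions of the genetic covariance function with their variance
## shares, and the area-under-trajectory ranking used for selection.
## Reads results/selected_fit.rds (run 03 first); writes
## results/trajectories.csv, results/eigenfunctions.csv,
## results/ranking.csv and, when ggplot2 is available, figures under
## results/figs/.

suppressPackageStartupMessages(library(rrtraj))

fit <- readRDS("results/selected_fit.rds")
grid_t <- time_grid(101)

traj <- predict_trajectory(fit, times = grid_t)
traj_tab <- data.frame(
  scaled_time = rep(grid_t, times = ncol(traj)),
  unit = rep(colnames(traj), each = length(grid_t)),
  genetic_value = as.numeric(traj)
)
write.csv(traj_tab, "results/trajectories.csv", row.names = FALSE,
          quote = FALSE)

eig <- eigenfunctions(fit$covs$genetic, times = grid_t)
eig_tab <- data.frame(
  scaled_time = rep(grid_t, times = ncol(eig$functions)),
  eigenfunction = rep(colnames(eig$functions), each = length(grid_t)),
  value = as.numeric(eig$functions)
)
write.csv(eig_tab, "results/eigenfunctions.csv", row.names = FALSE,
          quote = FALSE)
cat("eigenvalues of the genetic coefficient covariance:\n")
print(data.frame(eigenvalue = round(eig$values, 4),
                 proportion = round(eig$proportions, 4)), row.names = FALSE)

rk <- rank_units(fit)
write.csv(as.data.frame(rk), "results/ranking.csv", row.names = FALSE,
          quote = FALSE)
cat(sprintf("\nareas under the genetic trajectories: %.4f to %.4f\n",
            min(rk$area), max(rk$area)))
cat("top ten families by area:\n")
print(as.data.frame(rk[1:10, ]), row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figs", showWarnings = FALSE)
  p1 <- ggplot(traj_tab, aes(scaled_time, genetic_value, group = unit)) +
    geom_line(alpha = 0.4, linewidth = 0.3) +
    labs(x = "scaled harvest time", y = "genetic value (kg/plant)",
         title = "Genetic trajectories of the half-sib families") +
    theme_minimal()
  ggsave("results/figs/trajectories.png", p1, width = 7, height = 4.5,
         dpi = 150)
  p2 <- ggplot(eig_tab, aes(scaled_time, value, colour = eigenfunction)) +
    geom_line(linewidth = 0.7) +
    labs(x = "scaled harvest time", y = "eigenfunction value",
         title = "Eigenfunctions of the genetic covariance function") +
    theme_minimal()
  ggsave("results/figs/eigenfunctions.png", p2, width = 7, height = 4.5,
         dpi = 150)
  cat("\nfigures written under results/figs/\n")
}
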