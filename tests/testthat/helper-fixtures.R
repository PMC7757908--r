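## Shared fixtures: small simulated trials and random model parameters.

## A compact trial: nf half-sib families, 2 replications, `plants` plants
## per plot, J harvests, degree-1 genetic / degree-0 plot and permanent
## environment truth with diagonal residuals.
small_trial <- function(seed = 1, nf = 15, plants = 2, J = 3,
                        K_g = matrix(c(0.3, 0.05, 0.05, 0.1), 2),
                        K_s = matrix(0.1), K_p = matrix(0.08),
                        residual = "diagonal",
                        sigma2_res = NULL, missing_prob = 0) {
  years <- 2010:(2009 + J)
  if (is.null(sigma2_res)) {
    sigma2_res <- switch(residual,
      homogeneous = 0.3,
      diagonal = seq(0.2, 0.4, length.out = J),
      unstructured = 0.1 + diag(seq(0.2, 0.4, length.out = J)))
  }
  sim_config(n_families = nf, plants_per_plot = plants,
             harvest_years = years, K_g = K_g, K_s = K_s, K_p = K_p,
             residual = residual, sigma2_res = sigma2_res,
             cell_means = seq_len(J), missing_prob = missing_prob,
             seed = seed)
}

## Random symmetric positive-definite matrix of order p.
random_psd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  scale * (crossprod(A) / p + diag(0.1, p))
}

## A random tiny instance (<= ~50 observations) with random PSD covariance
## parameters, for likelihood-oracle comparisons.
random_instance <- function(seed) {
  set.seed(seed)
  J <- sample(2:4, 1)
  nf <- sample(3:5, 1)
  residual <- sample(c("homogeneous", "diagonal", "unstructured"), 1)
  cfg <- small_trial(seed = seed, nf = nf, plants = 1, J = J,
                     residual = residual,
                     missing_prob = sample(c(0, 0.15), 1))
  sim <- simulate_trial(cfg)
  dg <- sample(0:(J - 1), 1)
  bundle <- build_design(sim$records,
                         rr_config(dg, 0, 0, residual = residual))
  covs <- list(genetic = random_psd(dg + 1),
               perm = random_psd(1),
               plot = random_psd(1))
  resid <- switch(residual,
    homogeneous = residual_model("homogeneous", 0.2 + runif(1)),
    diagonal = residual_model("diagonal", 0.2 + runif(J)),
    unstructured = residual_model("unstructured", random_psd(J, 0.5)))
  list(bundle = bundle, covs = covs, resid = resid)
}
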