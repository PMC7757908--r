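test_that("MME likelihood equals the dense variance-matrix formula", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    l_mme <- reml_loglik(inst$bundle, inst$covs, inst$resid)
    l_dir <- reml_loglik_direct(inst$bundle, inst$covs, inst$resid)
    expect_equal(l_mme, l_dir, tolerance = 1e-6,
                 label = sprintf("mme loglik (seed %d)", seed))
  }
})

test_that("REML is invariant to shifts in the fixed-effect column space", {
  inst <- random_instance(101)
  l0 <- reml_loglik(inst$bundle, inst$covs, inst$resid)
  set.seed(7)
  shift <- as.numeric(inst$bundle$X %*% rnorm(ncol(inst$bundle$X), sd = 5))
  b2 <- inst$bundle
  b2$y <- b2$y + shift
  l1 <- reml_loglik(b2, inst$covs, inst$resid)
  expect_equal(l0, l1, tolerance = 1e-8)
})

test_that("equal-variance diagonal residual collapses to homogeneous", {
  cfg <- small_trial(seed = 21)
  sim <- simulate_trial(cfg)
  covs <- list(genetic = cfg$K_g, perm = cfg$K_p, plot = cfg$K_s)
  l_diag <- reml_loglik(build_design(sim$records, rr_config(1, 0, 0)),
                        covs, residual_model("diagonal", rep(0.3, 3)))
  l_hom <- reml_loglik(
    build_design(sim$records, rr_config(1, 0, 0, residual = "homogeneous")),
    covs, residual_model("homogeneous", 0.3))
  expect_equal(l_diag, l_hom, tolerance = 1e-10)
})

test_that("simulating with zero plot variance drives the estimate to the boundary", {
  cfg <- small_trial(seed = 22, nf = 30, plants = 3, J = 3,
                     K_s = matrix(0))
  sim <- simulate_trial(cfg)
  fit <- fit_reml(build_design(sim$records, rr_config(1, 0, 0)))
  expect_lt(fit$covs$plot[1, 1], 1e-3)
  expect_true(fit$boundary)
})

test_that("EM-only and AI runs reach the same optimum on an interior instance", {
  cfg <- small_trial(seed = 11, nf = 30, plants = 4, J = 4,
                     K_g = matrix(c(0.4, 0.08, 0.08, 0.15), 2),
                     K_s = matrix(0.3), K_p = matrix(0.2))
  sim <- simulate_trial(cfg)
  b <- build_design(sim$records, rr_config(1, 0, 0))
  f_ai <- fit_reml(b, algorithm = "ai-em")
  f_em <- fit_reml(b, algorithm = "em", max_iter = 3000, tol = 1e-10)
  expect_lt(abs(f_ai$loglik - f_em$loglik), 1e-4)
  expect_true(f_ai$converged)
})

test_that("accepted EM iterations never decrease the likelihood", {
  cfg <- small_trial(seed = 23)
  sim <- simulate_trial(cfg)
  fit <- fit_reml(build_design(sim$records, rr_config(1, 0, 0)),
                  algorithm = "em", max_iter = 80, tol = 1e-10)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
})

test_that("the MME solution satisfies the Henderson system", {
  inst <- random_instance(55)
  mme <- solve_mme(inst$bundle, inst$covs, inst$resid)
  expect_lt(mme$relative_residual, 1e-8)
})

test_that("genetic BLUPs vanish as the genetic variance shrinks to zero", {
  cfg <- small_trial(seed = 24)
  sim <- simulate_trial(cfg)
  b <- build_design(sim$records, rr_config(1, 0, 0))
  mme <- solve_mme(b, list(genetic = diag(1e-10, 2), perm = cfg$K_p,
                           plot = cfg$K_s),
                   residual_model("diagonal", cfg$sigma2_res))
  expect_lt(max(abs(mme$blup$genetic)), 1e-6)
})

test_that("a two-harvest degree-0 toy matches a hand-built Henderson system", {
  ## 2 families x 1 individual x 2 harvests, intercept-only effects;
  ## the dense mixed-model equations are assembled from first principles.
  rec <- data.frame(
    individual_id = rep(c("i1", "i2"), each = 2),
    family_id = rep(c("f1", "f2"), each = 2),
    replication = "1",
    plot_id = rep(c("p1", "p2"), each = 2),
    harvest_year = rep(c(2010, 2011), 2),
    value = c(1.0, 2.0, 1.5, 2.5)
  )
  s2g <- 0.4; s2p <- 0.3; s2s <- 0.2; s2e <- 0.5
  covs <- list(genetic = matrix(s2g), perm = matrix(s2p),
               plot = matrix(s2s))
  b <- build_design(rec, rr_config(0, 0, 0, residual = "homogeneous"))
  mme <- solve_mme(b, covs, residual_model("homogeneous", s2e))
  ## independent dense construction (phi0 = 1/sqrt(2))
  phi0 <- 1 / sqrt(2)
  X <- b$X
  Zg <- matrix(0, 4, 2); Zg[1:2, 1] <- phi0; Zg[3:4, 2] <- phi0
  T <- cbind(X, Zg, Zg, Zg)  # individual == plot == family blocks here
  Ginv <- diag(c(rep(0, ncol(X)), rep(1 / s2g, 2), rep(1 / s2p, 2),
                 rep(1 / s2s, 2)))
  C <- crossprod(T) / s2e + Ginv
  sol <- solve(C, crossprod(T, b$y) / s2e)
  k <- ncol(X)
  expect_equal(as.numeric(mme$blup$genetic), as.numeric(sol[k + 1:2]),
               tolerance = 1e-8)
  expect_equal(as.numeric(mme$blup$perm), as.numeric(sol[k + 3:4]),
               tolerance = 1e-8)
  expect_equal(unname(mme$blue), as.numeric(sol[1:k]), tolerance = 1e-8)
})

test_that("PEV blocks are dominated by the prior genetic covariance", {
  cfg <- small_trial(seed = 26, nf = 12, plants = 2, J = 3,
                     missing_prob = 0.2)
  sim <- simulate_trial(cfg)
  fit <- fit_reml(build_design(sim$records, rr_config(1, 0, 0)))
  for (u in seq_len(dim(fit$pev_genetic)[3])) {
    P <- fit$pev_genetic[, , u]
    expect_true(all(eigen(P, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
    gap <- eigen(fit$covs$genetic - P, symmetric = TRUE,
                 only.values = TRUE)$values
    expect_true(all(gap > -1e-8))
  }
})

test_that("units with fewer observed harvests have larger PEV", {
  cfg <- small_trial(seed = 27, nf = 20, plants = 2, J = 3)
  sim <- simulate_trial(cfg)
  rec <- sim$records
  ## family F01 keeps only the first harvest
  drop <- rec$family_id == "F01" & rec$harvest_year > 2010
  rec <- rec[!drop, ]
  b <- build_design(rec, rr_config(1, 0, 0))
  covs <- list(genetic = cfg$K_g, perm = cfg$K_p, plot = cfg$K_s)
  mme <- solve_mme(b, covs, residual_model("diagonal", cfg$sigma2_res))
  traces <- apply(mme$pev_genetic, 3, function(P) sum(diag(P)))
  expect_gt(traces[["F01"]], max(traces[names(traces) != "F01"]))
})

test_that("parameter recovery on a moderate trial is within sampling error", {
  ## one larger replicate; the replicated Monte-Carlo check lives in the
  ## acceptance suite
  cfg <- small_trial(seed = 30, nf = 80, plants = 4, J = 4,
                     K_s = matrix(0.25), K_p = matrix(0.2))
  sim <- simulate_trial(cfg)
  fit <- fit_reml(build_design(sim$records, rr_config(1, 0, 0)))
  expect_true(fit$converged)
  expect_equal(fit$covs$plot[1, 1], 0.25, tolerance = 0.5)
  expect_equal(fit$covs$perm[1, 1], 0.2, tolerance = 0.5)
  expect_equal(unname(diag(fit$covs$genetic)), unname(diag(cfg$K_g)),
               tolerance = 0.6)
  expect_equal(fit$residual$par, cfg$sigma2_res, tolerance = 0.25)
})

test_that("zeroed-incidence designs reproduce the reduced-model likelihood", {
  cfg <- small_trial(seed = 33, nf = 10)
  sim <- simulate_trial(cfg)
  b <- build_design(sim$records, rr_config(1, 0, 0))
  covs <- list(genetic = cfg$K_g, perm = cfg$K_p, plot = cfg$K_s)
  resid <- residual_model("diagonal", cfg$sigma2_res)
  ## oracle: dense formula with the plot covariance set to (numerically) zero
  covs0 <- covs
  covs0$plot <- matrix(1e-14)
  l_direct <- reml_loglik_direct(b, covs0, resid)
  l_dropped <- reml_loglik(drop_effect(b, "plot"), covs, resid)
  expect_equal(l_dropped, l_direct, tolerance = 1e-6)
  ## the reduced model never beats the full model at its own optimum
  f_full <- fit_reml(b)
  f_red <- fit_reml(drop_effect(b, "genetic"))
  expect_gte(f_full$loglik, f_red$loglik - 1e-6)
  test <- lrt(f_full$loglik, f_red$loglik,
              df = count_parameters(b$config, 3, by_effect = TRUE)[["genetic"]])
  expect_gte(test$statistic, 0)
  expect_lte(test$p_value, 1)
})
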