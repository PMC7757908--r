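## One small converged fit reused across the block.
fit_fixture <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      sim <- simulate_trial(small_trial(seed = 50, nf = 12, plants = 2,
                                        J = 3))
      value <<- fit_reml(build_design(sim$records, rr_config(1, 0, 0)))
    }
    value
  }
})

test_that("variance trajectories are quadratic forms in the basis", {
  tl <- scale_times(2010:2015)
  P2 <- legendre_matrix(tl, 2)
  expect_equal(variance_trajectory(matrix(0, 3, 3), P2), rep(0, 6))
  P0 <- legendre_matrix(tl, 0)
  expect_equal(variance_trajectory(matrix(2.4), P0), rep(1.2, 6))
  expect_equal(variance_trajectory(diag(3), P2), rowSums(P2^2))
  expect_error(variance_trajectory(diag(2), P2), "order of K")
})

test_that("per-harvest summaries reproduce published heritability ratios", {
  ## variance components of three mid-trial harvests of a published
  ## half-sib yield trial, entered as data
  s <- variance_summary(
    harvest = c(2011, 2012, 2013),
    sigma2_g = c(0.0042, 0.0172, 0.0565),
    sigma2_s = c(0.0338, 0.1879, 0.2736),
    sigma2_p = c(0.0083, 0.0209, 0.0415),
    sigma2_res = c(0.0231, 0.1079, 0.0988)
  )
  expect_equal(s$sigma2_phen, c(0.0694, 0.3339, 0.4704), tolerance = 1e-12)
  expect_equal(round(s$h2, 2), c(0.06, 0.05, 0.12))
  ## additivity is exact by construction
  expect_identical(s$sigma2_phen,
                   s$sigma2_g + s$sigma2_s + s$sigma2_p + s$sigma2_res)
})

test_that("heritability hits 1 when only genetic variance remains", {
  s <- variance_summary(1, sigma2_g = 0.5, sigma2_s = 0, sigma2_p = 0,
                        sigma2_res = 0)
  expect_equal(s$h2, 1)
})

test_that("zero PEV gives accuracy 1 and summary components add up", {
  fit <- fit_fixture()
  fit0 <- fit
  fit0$pev_genetic[] <- 0
  s0 <- summarize_fit(fit0)
  expect_equal(s0$accuracy, rep(1, 3))
  s <- summarize_fit(fit)
  expect_identical(s$sigma2_phen,
                   s$sigma2_g + s$sigma2_s + s$sigma2_p + s$sigma2_res)
  expect_true(all(s$h2 >= 0 & s$h2 <= 1))
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  expect_equal(s$mean, fit$bundle$harvest_means)
})

test_that("genetic correlations normalize the covariance function", {
  tl <- scale_times(2010:2015)
  P <- legendre_matrix(tl, 2)
  ## rank-1 coefficient covariance: all correlations +/-1
  v <- c(1, -0.5, 0.25)
  C1 <- genetic_correlations(tcrossprod(v), P)
  expect_equal(abs(unname(C1)), matrix(1, 6, 6), tolerance = 1e-10)
  set.seed(60)
  for (rep in 1:8) {
    K <- random_psd(3)
    C <- genetic_correlations(K, P, labels = tl$years)
    ## direct elementwise oracle
    O <- matrix(NA_real_, 6, 6)
    for (i in 1:6) {
      for (j in 1:6) {
        O[i, j] <- (P[i, ] %*% K %*% P[j, ]) /
          sqrt((P[i, ] %*% K %*% P[i, ]) * (P[j, ] %*% K %*% P[j, ]))
      }
    }
    expect_equal(unname(C), O, tolerance = 1e-12)
    expect_equal(diag(C), setNames(rep(1, 6), tl$years))
    expect_equal(C, t(C))
    expect_true(all(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("predicted trajectories are basis-weighted BLUP coefficients", {
  fit <- fit_fixture()
  tl <- fit$bundle$timeline
  tr <- predict_trajectory(fit, times = tl$scaled)
  Phi <- legendre_matrix(tl, 1)
  expect_equal(unname(tr), unname(Phi %*% fit$blup$genetic),
               tolerance = 1e-12)
  expect_error(predict_trajectory(fit, units = "nope"), "unknown genetic unit")
  ## degree-0 fit: constant trajectory alpha0 * phi0
  sim <- simulate_trial(small_trial(seed = 51, nf = 6))
  f0 <- fit_reml(build_design(sim$records, rr_config(0, 0, 0)))
  t0 <- predict_trajectory(f0, times = c(-1, 0, 1))
  expect_equal(t0[1, ], t0[3, ])
  expect_equal(unname(t0[2, ]),
               unname(f0$blup$genetic[1, ] / sqrt(2)), tolerance = 1e-12)
})

test_that("eigenfunctions decompose the genetic covariance function", {
  K <- matrix(c(0.5, 0, 0, 0.2), 2)
  e <- eigenfunctions(K, times = c(-1, 0, 1))
  expect_equal(e$values, c(0.5, 0.2))
  expect_equal(e$proportions, c(5 / 7, 2 / 7))
  Phi <- legendre_matrix(c(-1, 0, 1), 1)
  expect_equal(unname(e$functions[, 1]), unname(Phi[, 1]))
  expect_equal(unname(abs(e$functions[, 2])), unname(abs(Phi[, 2])))
  set.seed(61)
  for (rep in 1:6) {
    K <- random_psd(4)
    e <- eigenfunctions(K)
    expect_equal(sum(e$values), sum(diag(K)), tolerance = 1e-10)
    expect_equal(sum(e$proportions), 1, tolerance = 1e-12)
    ## spectral reconstruction
    R <- Reduce(`+`, lapply(seq_len(4), function(f) {
      e$values[f] * tcrossprod(e$vectors[, f])
    }))
    expect_equal(R, K, tolerance = 1e-10)
    ## eigenfunctions orthonormal under the L2[-1,1] inner product
    for (f1 in 1:2) {
      for (f2 in f1:2) {
        ip <- integrate(function(x) {
          B <- legendre_matrix(x, 3)
          (B %*% e$vectors[, f1]) * (B %*% e$vectors[, f2])
        }, -1, 1, rel.tol = 1e-10)$value
        expect_equal(ip, as.numeric(f1 == f2), tolerance = 1e-8)
      }
    }
  }
})

test_that("trajectory areas integrate the predicted genetic values", {
  fit <- fit_fixture()
  mu <- fit$bundle$grand_mean
  A <- trajectory_area(fit)
  ## quadrature oracle on the predicted trajectories
  for (u in names(A)[1:4]) {
    q <- integrate(function(x) {
      as.numeric(predict_trajectory(fit, units = u, times = x))
    }, -1, 1, rel.tol = 1e-12)$value
    expect_equal(unname(A[u]), mu + q, tolerance = 1e-10)
  }
  ## with the normalized basis only the intercept coefficient contributes
  expect_equal(unname(A), mu + sqrt(2) * unname(fit$blup$genetic[1, ]),
               tolerance = 1e-12)
  ## all-zero coefficients give the mean; linearity in the coefficients
  fit0 <- fit
  fit0$blup$genetic[] <- 0
  expect_equal(unname(trajectory_area(fit0)),
               rep(mu, ncol(fit$blup$genetic)))
  fit2 <- fit
  fit2$blup$genetic <- 2 * fit$blup$genetic
  expect_equal(unname(trajectory_area(fit2) - mu),
               2 * unname(A - mu), tolerance = 1e-10)
})

test_that("unit ranking is by descending area with deterministic ties", {
  fit <- fit_fixture()
  rk <- rank_units(fit)
  expect_setequal(rk$unit, colnames(fit$blup$genetic))
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$area) <= 1e-12))
  ## permuting unit columns does not change the ranking
  fitp <- fit
  perm <- rev(seq_len(ncol(fit$blup$genetic)))
  fitp$blup$genetic <- fit$blup$genetic[, perm]
  expect_identical(rank_units(fitp), rk)
  ## tie-break lexicographic on unit id
  fit_tie <- fit
  fit_tie$blup$genetic[] <- 0
  rk_tie <- rank_units(fit_tie)
  expect_identical(rk_tie$unit, sort(rk_tie$unit))
})
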