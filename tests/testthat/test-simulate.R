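test_that("identical seeds give identical trials, different seeds differ", {
  cfg <- small_trial(seed = 70, missing_prob = 0.1)
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$coefficients, s2$truth$coefficients)
  s3 <- simulate_trial(small_trial(seed = 71, missing_prob = 0.1))
  expect_false(identical(s1$records$value, s3$records$value))
})

test_that("the default layout reproduces the motivating trial dimensions", {
  sim <- simulate_trial(sim_config(seed = 1))
  rec <- sim$records
  expect_equal(nrow(rec), 73 * 2 * 5 * 6)  # 4380 records
  expect_equal(length(unique(rec$family_id)), 73L)
  expect_equal(length(unique(rec$individual_id)), 730L)
  expect_equal(length(unique(rec$plot_id)), 146L)
  expect_equal(sort(unique(rec$harvest_year)), 2010:2015)
  expect_true(all(table(rec$individual_id) == 6L))
})

test_that("invalid generating parameters are rejected", {
  expect_error(sim_config(K_g = matrix(c(1, 2, 2, 1), 2)), "PSD")
  expect_error(sim_config(missing_prob = 1), "missing_prob")
  expect_error(sim_config(harvest_years = 2010,
                          cell_means = 1), "J >= 2")
})

test_that("family-mean variance matches the generating components", {
  ## degree-0 truth: family variance 0.3, plot 0.1, perm 0.1, residual 0.2
  ## on the trait scale (coefficient variances are twice these because
  ## phi0^2 = 1/2); family means over 10 plants and 2 plots have variance
  ## 0.3 + 0.1/2 + (0.1 + 0.2)/10 = 0.38
  reps <- 30
  vhat <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_families = 300, n_replications = 2,
                      plants_per_plot = 5, harvest_years = 2010:2011,
                      K_g = matrix(0.6), K_s = matrix(0.2),
                      K_p = matrix(0.2), residual = "homogeneous",
                      sigma2_res = 0.2, cell_means = c(1, 2), seed = 700 + r)
    rec <- simulate_trial(cfg)$records
    rec <- rec[rec$harvest_year == 2010, ]
    var(tapply(rec$value, rec$family_id, mean))
  }, numeric(1))
  se <- sd(vhat) / sqrt(reps)
  expect_lt(abs(mean(vhat) - 0.38), 3 * se + 1e-8)
})

test_that("large simulations reproduce the generating variance trajectories", {
  cfg <- small_trial(seed = 72, nf = 500, plants = 1, J = 3)
  sim <- simulate_trial(cfg)
  tl <- sim$truth$timeline
  g_val <- sim$truth$coefficients$genetic %*% t(legendre_matrix(tl, 1))
  emp <- apply(g_val, 2, var)
  expected <- variance_trajectory(cfg$K_g, legendre_matrix(tl, 1))
  expect_equal(emp, expected, tolerance = 0.15)
})

test_that("missingness thins records at the requested rate", {
  cfg <- small_trial(seed = 73, nf = 100, plants = 5, missing_prob = 0.25)
  rec <- simulate_trial(cfg)$records
  frac <- 1 - nrow(rec) / (100 * 2 * 5 * 3)
  expect_equal(frac, 0.25, tolerance = 0.1)
  ## validation still passes with incomplete records
  expect_silent(validate_phenotypes(rec))
})

test_that("the truth manifest round-trips through JSON", {
  cfg <- small_trial(seed = 74, nf = 4)
  sim <- simulate_trial(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(sim$truth, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$n_families, 4)
  expect_equal(unname(as.matrix(m$K_g)), unname(cfg$K_g), tolerance = 1e-12)
  expect_equal(m$seed, cfg$seed)
  expect_equal(m$scaled_times, sim$truth$timeline$scaled)
})
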