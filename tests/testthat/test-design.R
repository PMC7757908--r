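## A hand-built 2-family, 4-individual, 2-harvest table.
tiny_records <- function() {
  expand.grid(individual_id = c("i1", "i2", "i3", "i4"),
              harvest_year = c(2010, 2011),
              stringsAsFactors = FALSE) |>
    transform(family_id = c("f1", "f1", "f2", "f2"),
              replication = c("1", "2", "1", "2"),
              plot_id = c("p1", "p2", "p3", "p4"),
              value = rnorm(8))
}

test_that("incidence dimensions follow the layout", {
  set.seed(1)
  rec <- tiny_records()
  b <- build_design(rec, rr_config(0, 0, 0, residual = "homogeneous"))
  expect_equal(b$n, 8L)
  expect_equal(ncol(b$Z), 2L)   # 2 families x 1 coefficient
  expect_equal(ncol(b$W), 4L)   # 4 individuals
  expect_equal(ncol(b$Q), 4L)   # 4 plots
  expect_equal(nrow(b$X), 8L)
  expect_equal(length(b$y), 8L)
})

test_that("random incidence rows carry the unit's basis values", {
  set.seed(2)
  rec <- rbind(tiny_records(),
               transform(tiny_records()[1:4, ], harvest_year = 2012,
                         value = rnorm(4)))
  b <- build_design(rec, rr_config(1, 0, 0))
  tl <- b$timeline
  expect_equal(tl$scaled, c(-1, 0, 1))
  Phi <- legendre_matrix(tl, 1)
  Zd <- as.matrix(b$Z)
  for (r in seq_len(b$n)) {
    fam <- b$records$family_id[r]
    block <- match(fam, b$units$genetic)
    cols <- (block - 1) * 2 + 1:2
    expect_equal(Zd[r, cols], unname(Phi[b$harvest[r], ]))
    expect_equal(sum(Zd[r, -cols] != 0), 0L)
  }
})

test_that("inconsistent tables and infeasible degrees are rejected", {
  set.seed(3)
  rec <- tiny_records()
  bad_plot <- rec
  bad_plot$plot_id[bad_plot$individual_id == "i1" &
                   bad_plot$harvest_year == 2011] <- "p9"
  expect_error(validate_phenotypes(bad_plot), "more than one plot")
  bad_fam <- rec
  bad_fam$family_id[5] <- "f2"
  expect_error(validate_phenotypes(bad_fam), "more than one family")
  dup <- rbind(rec, rec[1, ])
  expect_error(validate_phenotypes(dup), "duplicate record")
  bad_val <- rec
  bad_val$value[1] <- NA
  expect_error(validate_phenotypes(bad_val), "finite")
  expect_error(build_design(rec, rr_config(2, 0, 0)),
               "exceeds n_harvests - 1")
  extra <- cbind(rec, note = "x")
  expect_warning(validate_phenotypes(extra), "extra phenotype column")
})

test_that("covariance parameter counting matches the closed form", {
  expect_identical(count_parameters(rr_config(2, 5, 1,
                                              residual = "diagonal"), 6), 36L)
  expect_identical(count_parameters(rr_config(0, 0, 0,
                                              residual = "homogeneous"), 6),
                   4L)
  expect_identical(count_parameters(rr_config(0, 5, 0,
                                              residual = "diagonal"), 6), 29L)
  q <- count_parameters(rr_config(2, 5, 1, residual = "diagonal"), 6,
                        by_effect = TRUE)
  expect_identical(unname(q), c(6L, 21L, 3L, 6L))
  expect_identical(count_parameters(rr_config(1, 1, 1,
                                              residual = "unstructured"), 4),
                   3L * 3L + 10L)
})

test_that("fixed cell means are recovered from simulated data", {
  cfg <- small_trial(seed = 10, nf = 60, plants = 4, J = 3)
  sim <- simulate_trial(cfg)
  b <- build_design(sim$records, rr_config(1, 0, 0))
  mme <- solve_mme(b, list(genetic = cfg$K_g, perm = cfg$K_p,
                           plot = cfg$K_s),
                   residual_model("diagonal", cfg$sigma2_res))
  ## generating cell means: column rep within harvest
  truth <- as.numeric(t(cfg$cell_means))
  est <- unname(mme$blue[order(names(mme$blue))])
  truth <- truth[order(paste0("h", rep(2010:2012, each = 2), ":rep",
                              rep(1:2, 3)))]
  expect_equal(est, truth, tolerance = 0.12)
})

test_that("row permutation leaves the likelihood unchanged", {
  cfg <- small_trial(seed = 4)
  sim <- simulate_trial(cfg)
  set.seed(99)
  shuffled <- sim$records[sample(nrow(sim$records)), ]
  covs <- list(genetic = cfg$K_g, perm = cfg$K_p, plot = cfg$K_s)
  resid <- residual_model("diagonal", cfg$sigma2_res)
  l1 <- reml_loglik(build_design(sim$records, rr_config(1, 0, 0)), covs, resid)
  l2 <- reml_loglik(build_design(shuffled, rr_config(1, 0, 0)), covs, resid)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("phenotype CSVs round-trip", {
  sim <- simulate_trial(small_trial(seed = 6, nf = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(sim$records, path)
  back <- read_phenotypes(path)
  attr(back, "timeline") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(sim$records),
               tolerance = 1e-12)
})

test_that("scalar fixed layout is nested inside harvest-replication cells", {
  cfg <- small_trial(seed = 12, nf = 10, plants = 2, J = 3)
  sim <- simulate_trial(cfg)
  b_cells <- build_design(sim$records, rr_config(1, 0, 0))
  b_scalar <- build_design(sim$records,
                           rr_config(1, 0, 0, fixed_layout = "scalar"))
  ## scalar layout: replication effects + saturated common regression
  expect_lt(ncol(b_scalar$X), ncol(b_cells$X))
  ## every scalar-layout column lies in the span of the cell-means columns
  proj <- b_cells$X %*% qr.solve(b_cells$X, b_scalar$X)
  expect_lt(max(abs(proj - b_scalar$X)), 1e-8)
})
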