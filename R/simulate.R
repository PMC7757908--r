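#' Default generating covariances for the trial simulator
#'
#' Degree-1 coefficient covariances whose implied variance trajectories rise
#' over the six harvests with the magnitudes typical of a perennial-crop
#' yield trial (genetic variance from about 0.003 in the first harvest to
#' about 0.32 in the sixth, plot from 0.004 to 0.22, permanent environment
#' from 0.006 to 0.11), together with heterogeneous per-harvest residual
#' variances and harvest-by-replication cell means on the kg-per-plant scale.
#'
#' @return Named list with `K_g`, `K_s`, `K_p`, `sigma2_res` (length 6) and
#'   `cell_means` (6 harvests x 2 replications).
#' @export
default_truth <- function() {
  K_g <- matrix(c(0.14660, 0.09232,
                  0.09232, 0.06000), 2, 2)
  K_s <- matrix(c(0.110357, 0.061288,
                  0.061288, 0.036786), 2, 2)
  K_p <- matrix(c(0.056300, 0.029000,
                  0.029000, 0.018700), 2, 2)
  sigma2_res <- c(0.0020, 0.0231, 0.1079, 0.0988, 0.1368, 0.2154)
  mu <- c(0.201, 0.528, 1.488, 1.314, 2.050, 2.656)
  cell_means <- cbind(rep1 = mu - 0.05, rep2 = mu + 0.05)
  list(K_g = K_g, K_s = K_s, K_p = K_p, sigma2_res = sigma2_res,
       cell_means = cell_means)
}

#' Configuration of a synthetic half-sib progeny trial
#'
#' Describes a randomized complete block trial of half-sib families with one
#' plot of `plants_per_plot` individuals per family per replication,
#' trajectory-structured random effects and a chosen residual structure. The
#' defaults reproduce the motivating layout: 73 families, 2 replications,
#' 5 plants per plot (730 individuals, 146 plots), six annual harvests
#' 2010-2015, with the generating covariances of [default_truth()].
#'
#' @param n_families Number of half-sib families.
#' @param n_replications Number of replications (blocks).
#' @param plants_per_plot Individuals per plot; each family contributes one
#'   plot per replication.
#' @param harvest_years Calendar years of the harvests.
#' @param K_g,K_s,K_p True coefficient covariances (symmetric PSD) of the
#'   family, plot and permanent-environment trajectories; their orders set
#'   the generating polynomial degrees.
#' @param residual Residual structure used to draw residuals.
#' @param sigma2_res True residual parameters: scalar, per-harvest vector or
#'   harvest covariance matrix, matching `residual`.
#' @param cell_means Fixed harvest-by-replication means (matrix, harvests in
#'   rows); recycled across replications if a vector.
#' @param missing_prob Probability that any record is dropped (missing
#'   completely at random).
#' @param seed Master seed; one stream per effect is split from it so that
#'   adding one effect does not perturb the draws of another.
#' @return An object of class `rr_sim_config`.
#' @export
sim_config <- function(n_families = 73L, n_replications = 2L,
                       plants_per_plot = 5L,
                       harvest_years = 2010:2015,
                       K_g = default_truth()$K_g,
                       K_s = default_truth()$K_s,
                       K_p = default_truth()$K_p,
                       residual = c("diagonal", "homogeneous",
                                    "unstructured"),
                       sigma2_res = default_truth()$sigma2_res,
                       cell_means = default_truth()$cell_means,
                       missing_prob = 0,
                       seed = 1L) {
  residual <- match.arg(residual)
  J <- length(harvest_years)
  stopifnot(n_families >= 1L, n_replications >= 1L, plants_per_plot >= 1L,
            J >= 2L, missing_prob >= 0, missing_prob < 1)
  for (K in list(K_g, K_s, K_p)) {
    K <- as.matrix(K)
    if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8 * (1 + max(abs(K))) ||
        min(eigen((K + t(K)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8 * (1 + max(abs(K)))) {
      stop("true coefficient covariances must be symmetric PSD",
           call. = FALSE)
    }
    if (nrow(K) > J) {
      stop("true covariance order exceeds the number of harvests",
           call. = FALSE)
    }
  }
  if (is.vector(cell_means)) {
    stopifnot(length(cell_means) == J)
    cell_means <- matrix(cell_means, J, n_replications)
  }
  cell_means <- as.matrix(cell_means)
  stopifnot(nrow(cell_means) == J, ncol(cell_means) == n_replications)
  sigma2_res <- switch(residual,
    homogeneous = {
      stopifnot(length(sigma2_res) >= 1L, sigma2_res[1L] > 0)
      sigma2_res[1L]
    },
    diagonal = {
      if (length(sigma2_res) == 1L) sigma2_res <- rep(sigma2_res, J)
      stopifnot(length(sigma2_res) == J, all(sigma2_res > 0))
      sigma2_res
    },
    unstructured = {
      S <- as.matrix(sigma2_res)
      stopifnot(nrow(S) == J, ncol(S) == J)
      S
    })
  structure(
    list(n_families = as.integer(n_families),
         n_replications = as.integer(n_replications),
         plants_per_plot = as.integer(plants_per_plot),
         harvest_years = as.integer(harvest_years),
         K_g = as.matrix(K_g), K_s = as.matrix(K_s), K_p = as.matrix(K_p),
         residual = residual, sigma2_res = sigma2_res,
         cell_means = cell_means, missing_prob = missing_prob,
         seed = as.integer(seed)),
    class = "rr_sim_config"
  )
}

#' Simulate a half-sib progeny trial with trajectory-structured effects
#'
#' Generates one record per individual and harvest: the fixed
#' harvest-by-replication cell mean, plus the family, plot and individual
#' permanent-environment trajectories (coefficient vectors drawn from
#' zero-mean multivariate normals with the configured covariances, evaluated
#' through the normalized Legendre basis), plus a residual drawn under the
#' configured structure. Records are then dropped independently with the
#' missing probability. Identical configuration and seed give identical
#' output.
#'
#' @param config An [sim_config()].
#' @return List with `records` (tibble in the phenotype-table dialect) and
#'   `truth` (the generating parameters plus the realized coefficient draws).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "rr_sim_config"))
  J <- length(config$harvest_years)
  timeline <- scale_times(config$harvest_years)
  nf <- config$n_families
  nr <- config$n_replications
  pp <- config$plants_per_plot
  n_plots <- nf * nr
  n_ind <- nf * nr * pp

  fam_ids <- sprintf("F%02d", seq_len(nf))
  layout <- expand.grid(plant = seq_len(pp), rep = seq_len(nr),
                        fam = seq_len(nf))
  ind_id <- sprintf("F%02d.R%d.P%d", layout$fam, layout$rep, layout$plant)
  plot_id <- sprintf("F%02d.R%d", layout$fam, layout$rep)
  plot_ids <- unique(plot_id)

  ## one RNG stream per effect, split from the master seed
  draw <- function(k, expr) {
    set.seed(sub_seed(config$seed, k))
    expr()
  }
  g_coef <- draw(1L, function() rmvn(nf, config$K_g))          # nf x cg
  s_coef <- draw(2L, function() rmvn(n_plots, config$K_s))     # plots x cs
  p_coef <- draw(3L, function() rmvn(n_ind, config$K_p))       # ind x cp
  rownames(g_coef) <- fam_ids
  rownames(s_coef) <- plot_ids
  rownames(p_coef) <- ind_id

  Phi_g <- legendre_matrix(timeline, nrow(config$K_g) - 1L)
  Phi_s <- legendre_matrix(timeline, nrow(config$K_s) - 1L)
  Phi_p <- legendre_matrix(timeline, nrow(config$K_p) - 1L)

  ## n_ind x J matrices of effect values
  g_val <- g_coef[layout$fam, , drop = FALSE] %*% t(Phi_g)
  s_val <- s_coef[match(plot_id, plot_ids), , drop = FALSE] %*% t(Phi_s)
  p_val <- p_coef %*% t(Phi_p)

  resid_val <- draw(4L, function() {
    switch(config$residual,
      homogeneous = matrix(stats::rnorm(n_ind * J,
                                        sd = sqrt(config$sigma2_res)),
                           n_ind, J),
      diagonal = matrix(stats::rnorm(n_ind * J), n_ind, J,
                        byrow = FALSE) %*%
        diag(sqrt(config$sigma2_res), J),
      unstructured = rmvn(n_ind, config$sigma2_res))
  })

  fixed <- t(config$cell_means)[layout$rep, , drop = FALSE]  # n_ind x J
  value <- fixed + g_val + s_val + p_val + resid_val

  records <- tibble::tibble(
    individual_id = rep(ind_id, times = J),
    family_id = rep(fam_ids[layout$fam], times = J),
    replication = rep(as.character(layout$rep), times = J),
    plot_id = rep(plot_id, times = J),
    harvest_year = rep(config$harvest_years, each = n_ind),
    value = as.numeric(value)
  )
  if (config$missing_prob > 0) {
    keep <- draw(5L, function() {
      stats::runif(nrow(records)) >= config$missing_prob
    })
    records <- records[keep, , drop = FALSE]
  }
  records <- records[order(records$individual_id, records$harvest_year), ,
                     drop = FALSE]

  truth <- list(config = config, timeline = timeline,
                coefficients = list(genetic = g_coef, plot = s_coef,
                                    perm = p_coef))
  list(records = records, truth = truth)
}

#' Write the truth manifest of a simulated trial as JSON
#'
#' @param truth The `truth` element of [simulate_trial()] output.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  cfg <- truth$config
  manifest <- list(
    n_families = cfg$n_families,
    n_replications = cfg$n_replications,
    plants_per_plot = cfg$plants_per_plot,
    harvest_years = cfg$harvest_years,
    scaled_times = truth$timeline$scaled,
    K_g = cfg$K_g, K_s = cfg$K_s, K_p = cfg$K_p,
    residual = cfg$residual, sigma2_res = cfg$sigma2_res,
    cell_means = cfg$cell_means,
    missing_prob = cfg$missing_prob,
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
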