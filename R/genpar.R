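#' Variance trajectory implied by a coefficient covariance
#'
#' Evaluates \eqn{\sigma^2(t_j) = \phi_j K \phi_j'} for each row \eqn{\phi_j}
#' of the basis matrix: the per-time variance of a random regression effect
#' with coefficient covariance `K` on the original trait scale.
#'
#' @param K Symmetric coefficient covariance of order degree + 1.
#' @param basis Basis matrix from [legendre_matrix()], with matching column
#'   count.
#' @return Numeric vector of variances, one per basis row.
#' @export
variance_trajectory <- function(K, basis) {
  K <- as.matrix(K)
  if (ncol(basis) != nrow(K) || nrow(K) != ncol(K)) {
    stop("basis column count must equal the order of K", call. = FALSE)
  }
  rowSums((basis %*% K) * basis)
}

#' Assemble a per-harvest genetic-parameter table from variance components
#'
#' Combines per-harvest genetic, plot, permanent-environment and residual
#' variances into the phenotypic variance \eqn{\sigma^2_{phen} = \sigma^2_g +
#' \sigma^2_s + \sigma^2_p + \sigma^2_{res}}, heritability \eqn{h^2_g =
#' \sigma^2_g / \sigma^2_{phen}} and, when accuracies are supplied, the mean
#' selective accuracy. This is the assembly step shared by [summarize_fit()]
#' and direct use on published component tables.
#'
#' @param harvest Harvest labels (e.g. calendar years).
#' @param sigma2_g,sigma2_s,sigma2_p,sigma2_res Per-harvest variance
#'   components (genetic, plot, permanent environment, residual).
#' @param mean Optional per-harvest phenotypic means.
#' @param accuracy Optional per-harvest mean selective accuracies.
#' @return A tibble with columns `harvest`, the four components,
#'   `sigma2_phen`, `h2`, and optionally `accuracy` and `mean`.
#' @export
variance_summary <- function(harvest, sigma2_g, sigma2_s, sigma2_p,
                             sigma2_res, mean = NULL, accuracy = NULL) {
  phen <- sigma2_g + sigma2_s + sigma2_p + sigma2_res
  out <- tibble::tibble(
    harvest = harvest,
    sigma2_g = sigma2_g, sigma2_s = sigma2_s, sigma2_p = sigma2_p,
    sigma2_res = sigma2_res, sigma2_phen = phen,
    h2 = ifelse(phen > 0, sigma2_g / phen, NA_real_)
  )
  if (!is.null(accuracy)) out$accuracy <- accuracy
  if (!is.null(mean)) out$mean <- mean
  out
}

#' Per-harvest genetic parameters from a fitted model
#'
#' Transforms the estimated coefficient covariances into per-harvest variance
#' components via the covariance function \eqn{\phi K \phi'}, reads the
#' residual variance of each harvest from the fitted residual structure, and
#' derives heritability \eqn{h^2_g = \sigma^2_g/\sigma^2_{phen}} and mean
#' selective accuracy \eqn{r = \sqrt{1 - \phi\,PEV\,\phi'/\sigma^2_g}}
#' (averaged over genetic units, clipped to [0, 1]; reported as missing where
#' the genetic variance is zero).
#'
#' @param fit An [fit_reml()] result.
#' @return A tibble as returned by [variance_summary()], one row per harvest,
#'   including per-harvest phenotypic means of the data.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "rr_fit"))
  bundle <- fit$bundle
  tl <- bundle$timeline
  J <- length(tl$years)
  Phi_g <- legendre_matrix(tl$scaled, bundle$config$degree_genetic)
  Phi_s <- legendre_matrix(tl$scaled, bundle$config$degree_plot)
  Phi_p <- legendre_matrix(tl$scaled, bundle$config$degree_perm)
  sg <- variance_trajectory(fit$covs$genetic, Phi_g)
  ss <- variance_trajectory(fit$covs$plot, Phi_s)
  sp <- variance_trajectory(fit$covs$perm, Phi_p)
  sr <- resid_harvest_variances(fit$residual, J)

  nu <- dim(fit$pev_genetic)[3L]
  acc <- vapply(seq_len(J), function(j) {
    if (sg[j] <= 0) return(NA_real_)
    phi <- Phi_g[j, , drop = FALSE]
    r2 <- vapply(seq_len(nu), function(u) {
      1 - as.numeric(phi %*% fit$pev_genetic[, , u] %*% t(phi)) / sg[j]
    }, numeric(1))
    mean(sqrt(pmin(pmax(r2, 0), 1)))
  }, numeric(1))

  variance_summary(tl$years, sg, ss, sp, sr,
                   mean = bundle$harvest_means, accuracy = acc)
}

#' Genetic correlations between pairs of harvests
#'
#' Entry \eqn{(i, j)} is \eqn{\phi_i K \phi_j' / \sqrt{(\phi_i K \phi_i')
#' (\phi_j K \phi_j')}}: the correlation between the genetic effects of the
#' same unit at two harvests implied by the covariance function.
#'
#' @param K Symmetric PSD genetic coefficient covariance.
#' @param basis Basis matrix evaluated at the harvest times.
#' @param labels Optional row/column labels (default: basis row index).
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a zero-variance harvest are `NA`.
#' @export
genetic_correlations <- function(K, basis, labels = NULL) {
  G <- basis %*% as.matrix(K) %*% t(basis)
  v <- diag(G)
  d <- sqrt(ifelse(v > 0, v, NA_real_))
  C <- G / outer(d, d)
  diag(C) <- ifelse(v > 0, 1, NA_real_)
  if (!is.null(labels)) dimnames(C) <- list(labels, labels)
  C
}

#' Predicted genetic trajectory of one or more units
#'
#' Evaluates \eqn{\hat g_i(t) = \sum_m \hat\alpha_{im} \phi_m(t)}: the dot
#' product of a unit's BLUP coefficients with the basis at the requested
#' scaled times.
#'
#' @param fit An [fit_reml()] result.
#' @param units Character vector of genetic unit identifiers (default: all).
#' @param times Scaled times in \eqn{[-1, 1]} (default: a dense grid).
#' @return Matrix of genetic values, one row per time, one column per unit.
#' @export
predict_trajectory <- function(fit, units = NULL,
                               times = time_grid()) {
  stopifnot(inherits(fit, "rr_fit"))
  coefs <- fit$blup$genetic
  if (is.null(units)) units <- colnames(coefs)
  missing_units <- setdiff(units, colnames(coefs))
  if (length(missing_units) > 0L) {
    stop("unknown genetic unit(s): ",
         paste(utils::head(missing_units, 5), collapse = ", "), call. = FALSE)
  }
  Phi <- legendre_matrix(times, fit$bundle$config$degree_genetic)
  out <- Phi %*% coefs[, units, drop = FALSE]
  rownames(out) <- signif(times, 6)
  out
}

#' Eigenfunctions of the genetic covariance function
#'
#' Spectral decomposition of the genetic coefficient covariance \eqn{K_g}:
#' each eigenvector \eqn{c_f}, combined with the basis as \eqn{\Psi_f(t) =
#' \sum_m (c_f)_m \phi_m(t)}, is a deformation mode of the genetic
#' trajectories, and its eigenvalue share measures the fraction of genetic
#' variation attributable to that mode. With the normalized basis the
#' eigenfunctions are orthonormal under the \eqn{L^2[-1,1]} inner product.
#' Eigenvector signs are fixed so each vector's largest-magnitude entry is
#' positive.
#'
#' @param K Symmetric genetic coefficient covariance.
#' @param times Scaled times at which to evaluate the eigenfunctions.
#' @param normalized Basis normalization flag (default TRUE).
#' @return List with `values` (descending eigenvalues), `vectors`
#'   (coefficients, one column per eigenfunction), `proportions`
#'   (eigenvalue shares of the trace), `times` and `functions` (matrix of
#'   \eqn{\Psi_f(t)}, one column per eigenfunction).
#' @export
eigenfunctions <- function(K, times = time_grid(), normalized = TRUE) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K), max(abs(K - t(K))) < 1e-8 * (1 + max(abs(K))))
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  sgn <- apply(e$vectors, 2L, function(v) sign(v[which.max(abs(v))]))
  vectors <- sweep(e$vectors, 2L, ifelse(sgn == 0, 1, sgn), `*`)
  Phi <- legendre_matrix(times, degree = nrow(K) - 1L,
                         normalized = normalized)
  funs <- Phi %*% vectors
  colnames(funs) <- colnames(vectors) <- paste0("psi", seq_len(ncol(vectors)))
  list(values = e$values, vectors = vectors,
       proportions = e$values / sum(e$values),
       times = times, functions = funs)
}

#' Area under the genetic trajectory
#'
#' Computes \eqn{A_i = \mu + \int_{-1}^{1} \hat g_i(x)\,dx} for each genetic
#' unit: the phenotypic mean plus the exact integral of the predicted genetic
#' trajectory over scaled time, via the closed-form basis integrals (with the
#' normalized basis only the intercept coefficient contributes,
#' \eqn{\sqrt{2}\,\hat\alpha_{i0}}). Used as a selection index summarizing
#' performance over the whole trajectory.
#'
#' @param fit An [fit_reml()] result.
#' @param mu Phenotypic mean added to every area (default: grand mean of the
#'   data; a common additive constant does not affect ranking).
#' @param units Unit identifiers (default: all genetic units).
#' @return Named numeric vector of areas.
#' @export
trajectory_area <- function(fit, mu = NULL, units = NULL) {
  stopifnot(inherits(fit, "rr_fit"))
  if (is.null(mu)) mu <- fit$bundle$grand_mean
  coefs <- fit$blup$genetic
  if (is.null(units)) units <- colnames(coefs)
  missing_units <- setdiff(units, colnames(coefs))
  if (length(missing_units) > 0L) {
    stop("unknown genetic unit(s): ",
         paste(utils::head(missing_units, 5), collapse = ", "), call. = FALSE)
  }
  w <- basis_integrals(fit$bundle$config$degree_genetic)
  stats::setNames(mu + as.numeric(w %*% coefs[, units, drop = FALSE]), units)
}

#' Rank genetic units by area under their trajectories
#'
#' Orders units by descending trajectory area (rank 1 = largest area), with
#' deterministic lexicographic tie-breaking on the unit identifier.
#'
#' @inheritParams trajectory_area
#' @return A tibble with columns `unit`, `area`, `rank`.
#' @export
rank_units <- function(fit, mu = NULL) {
  areas <- trajectory_area(fit, mu = mu)
  ord <- order(-areas, names(areas), method = "radix")
  tibble::tibble(unit = names(areas)[ord],
                 area = as.numeric(areas[ord]),
                 rank = seq_along(areas))
}
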