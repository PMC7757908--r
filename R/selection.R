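#' Bayesian information criterion for a REML fit
#'
#' Computes \eqn{BIC = -2\,\mathrm{LogL} + p \,\ln(n - r_X)} where `p` is the
#' number of estimated covariance parameters, `n` the number of observations
#' and `rank_x` the rank of the fixed-effect incidence matrix. The natural
#' logarithm is used. Smaller is better.
#'
#' @param loglik Restricted log-likelihood at the optimum.
#' @param p Number of estimated covariance parameters (>= 1).
#' @param n Number of observations.
#' @param rank_x Rank of the fixed-effect design.
#' @return The BIC value.
#' @export
bic <- function(loglik, p, n, rank_x) {
  if (length(p) != 1L || is.na(p) || p < 1 || p != round(p)) {
    stop("p must be a positive integer", call. = FALSE)
  }
  if (n <= rank_x) {
    stop("n must exceed the fixed-effect rank", call. = FALSE)
  }
  -2 * loglik + p * log(n - rank_x)
}

#' Likelihood ratio test between nested models
#'
#' Statistic \eqn{2(\mathrm{LogL}_{full} - \mathrm{LogL}_{reduced})}, floored
#' at zero, referred to a chi-square upper tail with `df` degrees of freedom
#' (the number of covariance parameters dropped with the effect). The plain
#' chi-square reference ignores the boundary constraint on variance
#' parameters and is therefore conservative. Some software reports the
#' negated statistic \eqn{-2(\mathrm{LogL} - \mathrm{LogL}_R)}; only the sign
#' differs.
#'
#' @param loglik_full,loglik_reduced Restricted log-likelihoods of the full
#'   and reduced (nested) models on the same data.
#' @param df Degrees of freedom (>= 1).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(loglik_full, loglik_reduced, df) {
  if (length(df) != 1L || is.na(df) || df < 1 || df != round(df)) {
    stop("df must be a positive integer", call. = FALSE)
  }
  stat <- max(0, 2 * (loglik_full - loglik_reduced))
  list(statistic = stat, df = as.integer(df),
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Grid search over polynomial orders and residual structures
#'
#' Fits every combination of the requested Legendre degrees for the genetic,
#' plot and permanent-environment effects and residual structures, and ranks
#' the converged fits by BIC (ascending). Non-converged or failed cells are
#' retained with `converged = FALSE` and excluded from selection.
#'
#' @param records Phenotype table (see [validate_phenotypes()]).
#' @param timeline A `harvest_timeline`; default spans the observed years.
#' @param degrees_genetic,degrees_plot,degrees_perm Integer vectors of
#'   degrees to try.
#' @param residuals Character vector of residual structures to try.
#' @param genetic_unit Passed to [rr_config()].
#' @param keep_fits Logical; attach the fitted objects as the `fits`
#'   attribute (named by grid row).
#' @param warm_start Logical; fit the grid in increasing order of parameter
#'   count and initialize each model from the best already-converged fit
#'   whose degrees are componentwise nested in it (covariances padded or
#'   truncated, residual parameters converted between structures). Greatly
#'   reduces the risk of secondary likelihood optima in over-parameterized
#'   cells.
#' @param ... Passed to [fit_reml()] (e.g. `tol`, `max_iter`, `algorithm`).
#' @return A tibble with one row per grid cell: the degrees, residual
#'   structure, `df` (n minus fixed rank), `iterations`, `loglik`, per-effect
#'   parameter counts, total `p`, `bic`, `converged` and `selected` flags,
#'   sorted by BIC. The minimum-BIC converged row is flagged selected.
#' @export
rr_grid_search <- function(records, timeline = NULL,
                           degrees_genetic = 0:2, degrees_plot = 0:2,
                           degrees_perm = 0:2,
                           residuals = "diagonal",
                           genetic_unit = "family",
                           keep_fits = FALSE, warm_start = TRUE, ...) {
  grid <- expand.grid(degree_genetic = degrees_genetic,
                      degree_plot = degrees_plot,
                      degree_perm = degrees_perm,
                      residual = residuals,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty model grid", call. = FALSE)
  ## fit in increasing complexity so simpler optima can seed richer models
  n_harv <- length(if (is.null(timeline)) {
    unique(as.data.frame(records)$harvest_year)
  } else timeline$years)
  grid$p_tot <- vapply(seq_len(nrow(grid)), function(i) {
    count_parameters(rr_config(grid$degree_genetic[i], grid$degree_plot[i],
                               grid$degree_perm[i],
                               residual = grid$residual[i]), n_harv)
  }, integer(1))
  grid <- grid[order(grid$p_tot), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  fits <- list()
  done <- list()  # converged fits, for warm starts
  for (i in seq_len(nrow(grid))) {
    cfg <- rr_config(grid$degree_genetic[i], grid$degree_plot[i],
                     grid$degree_perm[i], residual = grid$residual[i],
                     genetic_unit = genetic_unit)
    bundle <- tryCatch(build_design(records, cfg, timeline),
                       error = function(e) e)
    fit <- if (inherits(bundle, "error")) bundle else tryCatch({
      init <- if (warm_start) warm_init(done, cfg, n_harv) else NULL
      f <- fit_reml(bundle, init = init, ...)
      if (!f$converged && !is.null(init)) {
        ## a warm start can park an awkward structure (e.g. unstructured
        ## residuals seeded from a boundary fit) in a bad region; retry cold
        f2 <- fit_reml(bundle, init = NULL, ...)
        if (f2$loglik > f$loglik) f <- f2
      }
      f
    }, error = function(e) e)
    if (!inherits(fit, "error") && fit$converged) {
      done[[length(done) + 1L]] <- fit
    }
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        degree_genetic = grid$degree_genetic[i],
        degree_plot = grid$degree_plot[i],
        degree_perm = grid$degree_perm[i],
        residual = grid$residual[i],
        df = NA_integer_, iterations = NA_integer_, loglik = NA_real_,
        p_genetic = NA_integer_, p_plot = NA_integer_, p_perm = NA_integer_,
        p_residual = NA_integer_, p = NA_integer_, bic = NA_real_,
        converged = FALSE, error = conditionMessage(fit),
        stringsAsFactors = FALSE)
      next
    }
    J <- length(fit$bundle$timeline$years)
    pq <- count_parameters(cfg, J, by_effect = TRUE)
    rows[[i]] <- data.frame(
      degree_genetic = grid$degree_genetic[i],
      degree_plot = grid$degree_plot[i],
      degree_perm = grid$degree_perm[i],
      residual = grid$residual[i],
      df = fit$n - fit$rank_x,
      iterations = fit$iterations,
      loglik = fit$loglik,
      p_genetic = pq[["genetic"]], p_plot = pq[["plot"]],
      p_perm = pq[["perm"]], p_residual = pq[["residual"]],
      p = sum(pq),
      bic = bic(fit$loglik, sum(pq), fit$n, fit$rank_x),
      converged = fit$converged, error = NA_character_,
      stringsAsFactors = FALSE)
    if (keep_fits) {
      fits[[paste(grid$degree_genetic[i], grid$degree_plot[i],
                  grid$degree_perm[i], grid$residual[i], sep = "_")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(!out$converged, out$bic), , drop = FALSE]
  rownames(out) <- NULL
  out$selected <- FALSE
  if (!any(out$converged)) {
    stop("no model in the grid converged", call. = FALSE)
  }
  out$selected[which(out$converged)[1L]] <- TRUE
  out <- tibble::as_tibble(out)
  if (keep_fits) attr(out, "fits") <- fits
  out
}

## Pad or truncate a coefficient covariance to a new order; padding adds a
## small diagonal so the matrix stays PD.
resize_cov <- function(K, c_new) {
  K <- as.matrix(K)
  c_old <- nrow(K)
  if (c_old == c_new) return(K)
  if (c_old > c_new) return(K[seq_len(c_new), seq_len(c_new), drop = FALSE])
  out <- diag(rep(1e-3 * mean(diag(K)) + 1e-12, c_new), c_new)
  out[seq_len(c_old), seq_len(c_old)] <- K
  out
}

## Convert residual parameters between structures.
resid_convert <- function(resid, structure, J) {
  v <- resid_harvest_variances(resid, J)
  par <- switch(structure,
    homogeneous = mean(v),
    diagonal = v,
    unstructured = if (resid$structure == "unstructured") resid$par
                   else diag(v, J))
  structure(list(structure = structure, par = par), class = "rr_residual")
}

## Starting values for a grid cell from the best converged fit whose
## degrees are componentwise nested in the target configuration.
warm_init <- function(done, cfg, J) {
  if (length(done) == 0L) return(NULL)
  nested <- Filter(function(f) {
    c0 <- f$bundle$config
    c0$degree_genetic <= cfg$degree_genetic &&
      c0$degree_plot <= cfg$degree_plot &&
      c0$degree_perm <= cfg$degree_perm
  }, done)
  if (length(nested) == 0L) return(NULL)
  best <- nested[[which.max(vapply(nested, function(f) f$loglik,
                                   numeric(1)))]]
  list(
    covs = list(
      genetic = resize_cov(best$covs$genetic, cfg$degree_genetic + 1L),
      perm = resize_cov(best$covs$perm, cfg$degree_perm + 1L),
      plot = resize_cov(best$covs$plot, cfg$degree_plot + 1L)
    ),
    resid = resid_convert(best$residual, cfg$residual, J)
  )
}
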