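#' Model configuration for a random regression fit
#'
#' Collects the polynomial degree of each random effect, the fixed-effect
#' layout, the residual covariance structure and the level at which genetic
#' effects are modelled.
#'
#' @param degree_genetic,degree_plot,degree_perm Legendre degree of the
#'   genetic, plot and permanent-environment random regressions (each between
#'   0 and number of harvests - 1).
#' @param fixed_layout `"cells"` for one fixed mean per observed
#'   harvest-by-replication combination (the default; it nests the
#'   alternative), or `"scalar"` for replication effects plus a common
#'   fixed Legendre regression of degree `n_harvests - 1` over time.
#' @param residual Residual covariance structure across harvests:
#'   `"homogeneous"` (one variance), `"diagonal"` (one variance per harvest)
#'   or `"unstructured"` (full harvest-by-harvest covariance, applied within
#'   individual).
#' @param genetic_unit `"family"` (default) treats half-sib families as the
#'   independent genetic units; `"individual"` attaches genetic coefficients
#'   to individuals (near-confounded with the permanent-environment effect
#'   unless a relationship structure distinguishes them — offered for
#'   completeness).
#' @return An object of class `rr_config` (a list of the validated fields).
#' @export
rr_config <- function(degree_genetic = 2L, degree_plot = 5L, degree_perm = 1L,
                      fixed_layout = c("cells", "scalar"),
                      residual = c("diagonal", "homogeneous", "unstructured"),
                      genetic_unit = c("family", "individual")) {
  fixed_layout <- match.arg(fixed_layout)
  residual <- match.arg(residual)
  genetic_unit <- match.arg(genetic_unit)
  for (d in list(degree_genetic, degree_plot, degree_perm)) {
    if (length(d) != 1L || is.na(d) || d < 0 || d != round(d)) {
      stop("polynomial degrees must be single non-negative integers",
           call. = FALSE)
    }
  }
  structure(
    list(degree_genetic = as.integer(degree_genetic),
         degree_plot = as.integer(degree_plot),
         degree_perm = as.integer(degree_perm),
         fixed_layout = fixed_layout,
         residual = residual,
         genetic_unit = genetic_unit),
    class = "rr_config"
  )
}

#' @export
print.rr_config <- function(x, ...) {
  cat(sprintf(
    "<rr_config> degrees g/s/p = %d/%d/%d, fixed = %s, residual = %s, unit = %s\n",
    x$degree_genetic, x$degree_plot, x$degree_perm,
    x$fixed_layout, x$residual, x$genetic_unit))
  invisible(x)
}

#' Validate a phenotype table
#'
#' Checks the tidy one-row-per-individual-per-harvest phenotype table against
#' the trial invariants: each individual belongs to exactly one family and
#' one plot, at most one record per individual and harvest, finite trait
#' values, and harvest years contained in the timeline.
#'
#' @param records Data frame with columns `individual_id`, `family_id`,
#'   `replication`, `plot_id`, `harvest_year`, `value`. Extra columns are
#'   ignored with a warning.
#' @param timeline A `harvest_timeline` (see [scale_times()]); defaults to
#'   the timeline spanned by the observed harvest years.
#' @return The validated records (invisibly), with identifier columns as
#'   character, sorted by individual then harvest year.
#' @export
validate_phenotypes <- function(records, timeline = NULL) {
  required <- c("individual_id", "family_id", "replication", "plot_id",
                "harvest_year", "value")
  records <- as.data.frame(records)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), required)
  if (length(extra) > 0L) {
    warning("ignoring extra phenotype column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    records <- records[required]
  }
  for (col in c("individual_id", "family_id", "replication", "plot_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  if (!is.numeric(records$value) || any(!is.finite(records$value))) {
    stop("trait values must be finite numbers", call. = FALSE)
  }
  if (is.null(timeline)) {
    timeline <- scale_times(sort(unique(records$harvest_year)))
  }
  if (!all(records$harvest_year %in% timeline$years)) {
    bad <- setdiff(unique(records$harvest_year), timeline$years)
    stop("harvest year(s) outside the trial timeline: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fam_per_ind <- tapply(records$family_id, records$individual_id,
                        function(v) length(unique(v)))
  if (any(fam_per_ind > 1L)) {
    stop("individual(s) assigned to more than one family: ",
         paste(utils::head(names(fam_per_ind)[fam_per_ind > 1L], 5),
               collapse = ", "), call. = FALSE)
  }
  plot_per_ind <- tapply(records$plot_id, records$individual_id,
                         function(v) length(unique(v)))
  if (any(plot_per_ind > 1L)) {
    stop("individual(s) assigned to more than one plot: ",
         paste(utils::head(names(plot_per_ind)[plot_per_ind > 1L], 5),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(records$individual_id, records$harvest_year, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate record(s) for the same individual and harvest",
         call. = FALSE)
  }
  records <- records[order(records$individual_id, records$harvest_year), ,
                     drop = FALSE]
  rownames(records) <- NULL
  attr(records, "timeline") <- timeline
  invisible(records)
}

#' Count estimated covariance parameters of a configuration
#'
#' Each random-regression effect of degree \eqn{M} contributes
#' \eqn{(M+1)(M+2)/2} free elements of its symmetric coefficient covariance;
#' the residual contributes 1 (homogeneous), \eqn{J} (diagonal) or
#' \eqn{J(J+1)/2} (unstructured) parameters for \eqn{J} harvests.
#'
#' @param config An [rr_config()].
#' @param n_harvests Number of harvests \eqn{J}.
#' @param by_effect Logical; return the per-effect breakdown instead of the
#'   total.
#' @return Integer total (or named integer vector when `by_effect = TRUE`).
#' @examples
#' count_parameters(rr_config(2, 5, 1, residual = "diagonal"), 6)  # 36
#' @export
count_parameters <- function(config, n_harvests, by_effect = FALSE) {
  stopifnot(inherits(config, "rr_config"))
  tri <- function(m) ((m + 1L) * (m + 2L)) %/% 2L
  q <- c(
    genetic = tri(config$degree_genetic),
    plot = tri(config$degree_plot),
    perm = tri(config$degree_perm),
    residual = switch(config$residual,
      homogeneous = 1L,
      diagonal = as.integer(n_harvests),
      unstructured = as.integer(n_harvests * (n_harvests + 1L) / 2L)
    )
  )
  if (by_effect) q else sum(q)
}

## Sparse random-regression incidence for one effect: row i carries the
## basis values phi_0..phi_c-1(t_i) in the column block of its unit.
rr_incidence <- function(unit, Phi) {
  unit <- factor(unit)
  n <- length(unit)
  c <- ncol(Phi)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = c),
    j = (rep(as.integer(unit), each = c) - 1L) * c + rep(seq_len(c), times = n),
    x = as.vector(t(Phi)),
    dims = c(n, nlevels(unit) * c)
  )
  attr(Z, "units") <- levels(unit)
  attr(Z, "n_coef") <- c
  Z
}

#' Assemble the mixed-model design from a phenotype table
#'
#' Builds the response vector, fixed-effect incidence and the sparse
#' random-regression incidence matrices for the genetic, permanent-environment
#' and plot effects, with rows grouped by individual and ordered by harvest
#' (the ordering assumed by the unstructured residual blocks).
#'
#' @inheritParams validate_phenotypes
#' @param config An [rr_config()].
#' @return An object of class `rr_design`: a list with `y`, `X`, sparse `Z`
#'   (genetic), `W` (permanent environment), `Q` (plot), per-row harvest and
#'   individual indices, per-harvest counts and means, `timeline`, `config`
#'   and the unit identifiers of each random effect.
#' @export
build_design <- function(records, config, timeline = NULL) {
  stopifnot(inherits(config, "rr_config"))
  records <- validate_phenotypes(records, timeline)
  timeline <- attr(records, "timeline")
  J <- length(timeline$years)
  max_deg <- J - 1L
  for (nm in c("degree_genetic", "degree_plot", "degree_perm")) {
    if (config[[nm]] > max_deg) {
      stop(nm, " = ", config[[nm]], " exceeds n_harvests - 1 = ", max_deg,
           call. = FALSE)
    }
  }
  y <- records$value
  n <- length(y)
  harvest <- match(records$harvest_year, timeline$years)
  t_obs <- timeline$scaled[harvest]

  if (config$fixed_layout == "cells") {
    cell <- factor(paste0("h", records$harvest_year, ":rep",
                          records$replication))
    X <- stats::model.matrix(~ cell - 1)
    colnames(X) <- levels(cell)
  } else {
    rep_f <- factor(records$replication)
    Xr <- stats::model.matrix(~ rep_f - 1)
    colnames(Xr) <- paste0("rep", levels(rep_f))
    Phi_fix <- legendre_matrix(t_obs, degree = max_deg)
    X <- cbind(Xr, Phi_fix[, -1L, drop = FALSE])
  }
  rank_x <- qr(X)$rank
  if (rank_x < ncol(X)) {
    keep <- qr(X)$pivot[seq_len(rank_x)]
    X <- X[, sort(keep), drop = FALSE]
  }

  genetic_unit <- if (config$genetic_unit == "family") {
    records$family_id
  } else {
    records$individual_id
  }
  Z <- rr_incidence(genetic_unit,
                    legendre_matrix(t_obs, config$degree_genetic))
  W <- rr_incidence(records$individual_id,
                    legendre_matrix(t_obs, config$degree_perm))
  Q <- rr_incidence(records$plot_id,
                    legendre_matrix(t_obs, config$degree_plot))

  structure(
    list(
      y = y, X = X, Z = Z, W = W, Q = Q,
      harvest = harvest,
      individual = factor(records$individual_id),
      n = n, rank_x = ncol(X),
      harvest_counts = tabulate(harvest, nbins = J),
      harvest_means = as.numeric(tapply(y, factor(harvest, levels = seq_len(J)),
                                        mean)),
      grand_mean = mean(y),
      timeline = timeline, config = config,
      units = list(genetic = attr(Z, "units"),
                   perm = attr(W, "units"),
                   plot = attr(Q, "units")),
      records = records
    ),
    class = "rr_design"
  )
}

#' @export
print.rr_design <- function(x, ...) {
  cat(sprintf(
    "<rr_design> %d obs, %d harvests, %d genetic units, %d individuals, %d plots\n",
    x$n, length(x$timeline$years), length(x$units$genetic),
    length(x$units$perm), length(x$units$plot)))
  cat(sprintf("  fixed columns: %d (%s layout), residual: %s\n",
              x$rank_x, x$config$fixed_layout, x$config$residual))
  invisible(x)
}

#' Reduced design without one random effect
#'
#' Returns a copy of the design in which the incidence matrix of the chosen
#' random effect is zeroed, so the effect contributes nothing to the model:
#' the restricted likelihood of a fit on the result is that of the reduced
#' model without that effect, as used in likelihood-ratio tests of the
#' genetic, permanent-environment or plot effect. The degrees of freedom of
#' such a test is the number of covariance parameters of the dropped effect.
#'
#' @param bundle An [build_design()] result.
#' @param effect One of `"genetic"`, `"perm"`, `"plot"`.
#' @return The modified `rr_design`.
#' @export
drop_effect <- function(bundle, effect = c("genetic", "perm", "plot")) {
  stopifnot(inherits(bundle, "rr_design"))
  effect <- match.arg(effect)
  slot <- switch(effect, genetic = "Z", perm = "W", plot = "Q")
  attrs <- attributes(bundle[[slot]])
  bundle[[slot]] <- bundle[[slot]] * 0
  attr(bundle[[slot]], "units") <- attrs$units
  attr(bundle[[slot]], "n_coef") <- attrs$n_coef
  bundle
}

#' Read a phenotype CSV
#'
#' Reads the tidy phenotype dialect (UTF-8, comma separated, '.' decimal,
#' header `individual_id, family_id, replication, plot_id, harvest_year,
#' value`) and validates it.
#'
#' @param path File path.
#' @return A validated phenotype data frame (see [validate_phenotypes()]).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- validate_phenotypes(df)
  attr_tl <- attr(out, "timeline")
  out <- tibble::as_tibble(out)
  attr(out, "timeline") <- attr_tl
  out
}

#' Write a phenotype CSV
#'
#' @param records Phenotype table.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
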