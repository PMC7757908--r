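#' Scale harvest years to the Legendre domain [-1, 1]
#'
#' Maps calendar harvest years affinely onto the interval \eqn{[-1, +1]} via
#' \eqn{t_x = -1 + 2 (h_x - h_{min}) / (h_{max} - h_{min})}, the standard
#' rescaling required before evaluating Legendre polynomials at harvest
#' times. The first harvest maps to -1 and the last to +1 exactly; spacing
#' between years is preserved.
#'
#' @param years Integer (or numeric) vector of calendar harvest years,
#'   strictly increasing, at least two distinct values.
#' @return An object of class `harvest_timeline`: a list with elements
#'   `years` and `scaled` (unitless times on \eqn{[-1, 1]}).
#' @examples
#' scale_times(2010:2015)$scaled
#' @export
scale_times <- function(years) {
  if (length(years) < 2L) {
    stop("need at least two harvest years", call. = FALSE)
  }
  if (anyNA(years) || !is.numeric(years)) {
    stop("harvest years must be numeric and non-missing", call. = FALSE)
  }
  if (any(diff(years) <= 0)) {
    if (length(unique(years)) == 1L) {
      stop("degenerate timeline: all harvest years identical", call. = FALSE)
    }
    stop("harvest years must be strictly increasing", call. = FALSE)
  }
  hmin <- years[1L]
  hmax <- years[length(years)]
  scaled <- -1 + 2 * (years - hmin) / (hmax - hmin)
  structure(
    list(years = as.numeric(years), scaled = as.numeric(scaled)),
    class = "harvest_timeline"
  )
}

#' @export
print.harvest_timeline <- function(x, ...) {
  cat("<harvest_timeline> ", length(x$years), " harvests: ",
      paste(x$years, collapse = ", "), "\n", sep = "")
  cat("  scaled: ", paste(signif(x$scaled, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate (normalized) Legendre polynomials
#'
#' Evaluates Legendre polynomials \eqn{P_0, \dots, P_M} at the supplied
#' points by the Bonnet three-term recurrence
#' \eqn{(m+1) P_{m+1}(x) = (2m+1) x P_m(x) - m P_{m-1}(x)}.
#' With `normalized = TRUE` (the default used throughout the package) each
#' column is scaled by \eqn{\sqrt{(2m+1)/2}} so the basis is orthonormal
#' under the \eqn{L^2[-1,1]} inner product — the convention used for
#' covariance functions, where it makes eigenfunction variance shares
#' well-defined.
#'
#' @param t Numeric vector of evaluation points (scaled times), or a
#'   `harvest_timeline` whose scaled times are used.
#' @param degree Maximum polynomial degree \eqn{M \ge 0}.
#' @param normalized Logical; scale each column by \eqn{\sqrt{(2m+1)/2}}.
#' @return A numeric matrix with `length(t)` rows and `degree + 1` columns;
#'   column `m + 1` holds \eqn{\phi_m(t)}. Attributes `degree` and
#'   `normalized` record the construction.
#' @examples
#' legendre_matrix(scale_times(2010:2015), degree = 2)
#' @export
legendre_matrix <- function(t, degree, normalized = TRUE) {
  if (inherits(t, "harvest_timeline")) t <- t$scaled
  if (!is.numeric(t) || anyNA(t)) {
    stop("evaluation points must be numeric and non-missing", call. = FALSE)
  }
  if (length(degree) != 1L || is.na(degree) || degree < 0 ||
      degree != round(degree)) {
    stop("degree must be a single non-negative integer", call. = FALSE)
  }
  degree <- as.integer(degree)
  n <- length(t)
  P <- matrix(0, n, degree + 1L)
  P[, 1L] <- 1
  if (degree >= 1L) P[, 2L] <- t
  if (degree >= 2L) {
    for (m in 1L:(degree - 1L)) {
      P[, m + 2L] <- ((2 * m + 1) * t * P[, m + 1L] - m * P[, m]) / (m + 1)
    }
  }
  if (normalized) {
    P <- sweep(P, 2L, sqrt((2 * seq_len(degree + 1L) - 1) / 2), `*`)
  }
  dimnames(P) <- list(NULL, paste0("phi", 0L:degree))
  attr(P, "degree") <- degree
  attr(P, "normalized") <- normalized
  P
}

#' Exact integrals of the Legendre basis over [-1, 1]
#'
#' Returns \eqn{\int_{-1}^{1} \phi_m(x)\,dx} for \eqn{m = 0, \dots, M}.
#' Every polynomial of degree \eqn{m \ge 1} is orthogonal to the constant,
#' so only the first entry is non-zero: \eqn{\sqrt{2}} for the normalized
#' basis, 2 otherwise. Used for the closed-form area under a predicted
#' trajectory.
#'
#' @inheritParams legendre_matrix
#' @return Numeric vector of length `degree + 1`.
#' @export
basis_integrals <- function(degree, normalized = TRUE) {
  if (length(degree) != 1L || is.na(degree) || degree < 0 ||
      degree != round(degree)) {
    stop("degree must be a single non-negative integer", call. = FALSE)
  }
  out <- numeric(degree + 1L)
  out[1L] <- if (normalized) sqrt(2) else 2
  names(out) <- paste0("phi", 0L:as.integer(degree))
  out
}

#' Dense evaluation grid on the scaled-time interval
#'
#' @param n Number of grid points (default 101).
#' @return Numeric vector of equally spaced points on \eqn{[-1, 1]}.
#' @export
time_grid <- function(n = 101L) seq(-1, 1, length.out = n)
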