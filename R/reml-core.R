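#' Residual covariance model
#'
#' Describes the residual covariance across harvests: a single variance
#' (`homogeneous`), one variance per harvest (`diagonal`), or a full
#' harvest-by-harvest covariance applied within each individual
#' (`unstructured`; observations of different individuals remain
#' uncorrelated).
#'
#' @param structure One of `"homogeneous"`, `"diagonal"`, `"unstructured"`.
#' @param par Scalar variance, vector of per-harvest variances, or symmetric
#'   positive-definite harvest covariance matrix, matching `structure`.
#' @return An object of class `rr_residual`.
#' @export
residual_model <- function(structure = c("homogeneous", "diagonal",
                                         "unstructured"), par) {
  structure <- match.arg(structure)
  if (structure == "homogeneous") {
    stopifnot(length(par) == 1L, is.finite(par), par > 0)
    par <- as.numeric(par)
  } else if (structure == "diagonal") {
    stopifnot(is.numeric(par), all(is.finite(par)), all(par > 0))
    par <- as.numeric(par)
  } else {
    par <- as.matrix(par)
    stopifnot(nrow(par) == ncol(par), all(is.finite(par)),
              max(abs(par - t(par))) < 1e-8 * (1 + max(abs(par))))
    par <- (par + t(par)) / 2
    if (min(eigen(par, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("unstructured residual covariance must be positive definite",
           call. = FALSE)
    }
  }
  structure(list(structure = structure, par = par), class = "rr_residual")
}

## Per-harvest residual variances implied by a residual model.
resid_harvest_variances <- function(resid, J) {
  switch(resid$structure,
    homogeneous = rep(resid$par, J),
    diagonal = {
      stopifnot(length(resid$par) == J)
      resid$par
    },
    unstructured = diag(resid$par)
  )
}

## Sparse R^{-1} for the whole data vector plus log|R|. Rows are grouped by
## individual and ordered by harvest (guaranteed by build_design), so the
## unstructured case is block diagonal with one block per individual,
## subset to its observed harvests. Blocks are cached per observation
## pattern.
resid_rinv <- function(resid, bundle) {
  n <- bundle$n
  h <- bundle$harvest
  J <- length(bundle$timeline$years)
  if (resid$structure == "homogeneous") {
    s2 <- resid$par
    return(list(Rinv = Matrix::Diagonal(n, 1 / s2), logdet = n * log(s2)))
  }
  if (resid$structure == "diagonal") {
    s2 <- resid$par
    stopifnot(length(s2) == J)
    return(list(Rinv = Matrix::Diagonal(n, 1 / s2[h]),
                logdet = sum(bundle$harvest_counts * log(s2))))
  }
  Sig <- resid$par
  stopifnot(nrow(Sig) == J)
  ind <- bundle$individual
  rows_by_ind <- split(seq_len(n), ind)
  cache <- new.env(parent = emptyenv())
  ii <- jj <- xx <- vector("list", length(rows_by_ind))
  logdet <- 0
  for (k in seq_along(rows_by_ind)) {
    rows <- rows_by_ind[[k]]
    hs <- h[rows]
    key <- paste(hs, collapse = ",")
    blk <- cache[[key]]
    if (is.null(blk)) {
      S <- Sig[hs, hs, drop = FALSE]
      ch <- chol(S)
      blk <- list(inv = chol2inv(ch), ld = 2 * sum(log(diag(ch))))
      cache[[key]] <- blk
    }
    logdet <- logdet + blk$ld
    m <- length(rows)
    ii[[k]] <- rep(rows, times = m)
    jj[[k]] <- rep(rows, each = m)
    xx[[k]] <- as.vector(blk$inv)
  }
  Rinv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n))
  list(Rinv = Rinv, logdet = logdet)
}

## Precompute the pieces of the mixed-model equations that do not change
## across REML iterations: the stacked incidence T = [X Z W Q], column
## offsets per effect, and per-harvest cross-products used for residual
## derivatives.
mme_precompute <- function(bundle) {
  X <- Matrix::Matrix(bundle$X, sparse = TRUE)
  T <- cbind(X, bundle$Z, bundle$W, bundle$Q)
  px <- ncol(X)
  eff <- list(
    genetic = list(Z = bundle$Z, units = bundle$units$genetic),
    perm = list(Z = bundle$W, units = bundle$units$perm),
    plot = list(Z = bundle$Q, units = bundle$units$plot)
  )
  offset <- px
  for (nm in names(eff)) {
    q <- length(eff[[nm]]$units)
    c <- ncol(eff[[nm]]$Z) / q
    eff[[nm]]$q <- q
    eff[[nm]]$c <- as.integer(c)
    eff[[nm]]$offset <- offset
    eff[[nm]]$cols <- offset + seq_len(q * c)
    offset <- offset + q * c
  }
  J <- length(bundle$timeline$years)
  rows_by_harvest <- split(seq_len(bundle$n), bundle$harvest)
  list(T = T, px = px, eff = eff, p_total = offset, J = J,
       rows_by_harvest = rows_by_harvest)
}

## Evaluate the restricted log-likelihood (and optionally the dense inverse
## of the MME coefficient matrix) at the given covariance parameters via the
## mixed-model-equations identity
##   -2 logL = log|R| + log|G| + log|C| + y'Py + (n - rank X) log 2pi.
mme_eval <- function(bundle, pre, covs, resid, want_inverse = FALSE) {
  n <- bundle$n
  y <- bundle$y
  ri <- resid_rinv(resid, bundle)
  U <- ri$Rinv %*% pre$T
  Cd <- as.matrix(Matrix::crossprod(pre$T, U))
  logdetG <- 0
  Kinv <- list()
  for (nm in names(pre$eff)) {
    e <- pre$eff[[nm]]
    K <- as.matrix(covs[[nm]])
    stopifnot(nrow(K) == e$c)
    ch <- tryCatch(chol(K), error = function(err) NULL)
    if (is.null(ch)) return(list(ok = FALSE, loglik = -Inf))
    Ki <- chol2inv(ch)
    Kinv[[nm]] <- Ki
    logdetG <- logdetG + e$q * 2 * sum(log(diag(ch)))
    for (a in seq_len(e$c)) {
      ia <- e$offset + (seq_len(e$q) - 1L) * e$c + a
      for (b in seq_len(e$c)) {
        ib <- e$offset + (seq_len(e$q) - 1L) * e$c + b
        idx <- cbind(ia, ib)
        Cd[idx] <- Cd[idx] + Ki[a, b]
      }
    }
  }
  ry <- as.numeric(ri$Rinv %*% y)
  rhs <- as.numeric(Matrix::crossprod(pre$T, ry))
  cholC <- tryCatch(chol(Cd), error = function(err) NULL)
  if (is.null(cholC)) return(list(ok = FALSE, loglik = -Inf))
  sol <- backsolve(cholC, backsolve(cholC, rhs, transpose = TRUE))
  yPy <- sum(y * ry) - sum(sol * rhs)
  logdetC <- 2 * sum(log(diag(cholC)))
  loglik <- -0.5 * (ri$logdet + logdetG + logdetC + yPy +
                    (n - pre$px) * log(2 * pi))
  out <- list(ok = TRUE, loglik = loglik, sol = sol, rhs = rhs,
              Rinv = ri$Rinv, logdetR = ri$logdet, Kinv = Kinv,
              cholC = cholC, yPy = yPy)
  out$ehat <- as.numeric(y - pre$T %*% sol)
  out$Py <- as.numeric(ri$Rinv %*% out$ehat)
  if (want_inverse) out$Cinv <- chol2inv(cholC)
  out
}

#' Restricted log-likelihood at given covariance parameters
#'
#' Evaluates the REML log-likelihood of a design at fixed coefficient
#' covariances and residual model through the mixed-model-equations identity,
#' including the \eqn{-\tfrac{1}{2}(n - r_X)\log 2\pi} constant so values are
#' comparable across residual structures on the same data.
#'
#' @param bundle An [build_design()] result.
#' @param covs Named list with symmetric PSD matrices `genetic`, `perm`,
#'   `plot` of orders degree + 1.
#' @param resid A [residual_model()].
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(bundle, covs, resid) {
  stopifnot(inherits(bundle, "rr_design"), inherits(resid, "rr_residual"))
  pre <- mme_precompute(bundle)
  ev <- mme_eval(bundle, pre, covs, resid)
  if (!ev$ok) stop("coefficient matrix not positive definite at the supplied parameters",
                   call. = FALSE)
  ev$loglik
}

#' Restricted log-likelihood via the dense variance-matrix formula
#'
#' Reference implementation of the REML log-likelihood that forms the full
#' phenotypic covariance \eqn{V = Z (I \otimes K_g) Z' + W (I \otimes K_p) W'
#' + Q (I \otimes K_s) Q' + R} explicitly and evaluates
#' \eqn{-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py + (n - r_X)\log 2\pi]}.
#' Intended for validation on small problems; it is an independent code path
#' from the mixed-model-equations evaluator used by [fit_reml()].
#'
#' @inheritParams reml_loglik
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik_direct <- function(bundle, covs, resid) {
  stopifnot(inherits(bundle, "rr_design"), inherits(resid, "rr_residual"))
  n <- bundle$n
  J <- length(bundle$timeline$years)
  blockdiag_units <- function(Z, K) {
    q <- ncol(Z) / nrow(K)
    G <- Matrix::bdiag(rep(list(Matrix::Matrix(K)), q))
    as.matrix(Z %*% G %*% Matrix::t(Z))
  }
  V <- blockdiag_units(bundle$Z, as.matrix(covs$genetic)) +
    blockdiag_units(bundle$W, as.matrix(covs$perm)) +
    blockdiag_units(bundle$Q, as.matrix(covs$plot))
  h <- bundle$harvest
  if (resid$structure == "homogeneous") {
    V <- V + diag(rep(resid$par, n))
  } else if (resid$structure == "diagonal") {
    V <- V + diag(resid$par[h])
  } else {
    for (rows in split(seq_len(n), bundle$individual)) {
      V[rows, rows] <- V[rows, rows] +
        resid$par[h[rows], h[rows], drop = FALSE]
    }
  }
  X <- bundle$X
  y <- bundle$y
  chV <- chol(V)
  Vinv_y <- backsolve(chV, backsolve(chV, y, transpose = TRUE))
  Vinv_X <- backsolve(chV, backsolve(chV, X, transpose = TRUE))
  XtVinvX <- crossprod(X, Vinv_X)
  chXVX <- chol(XtVinvX)
  beta <- backsolve(chXVX, backsolve(chXVX, crossprod(X, Vinv_y),
                                     transpose = TRUE))
  yPy <- sum(y * Vinv_y) - sum(crossprod(X, Vinv_y) * beta)
  -0.5 * (2 * sum(log(diag(chV))) + 2 * sum(log(diag(chXVX))) + yPy +
          (n - ncol(X)) * log(2 * pi))
}
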