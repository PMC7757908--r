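## trace(A %*% B) for sparse symmetric-pattern A and dense B, via the
## triplet representation of A.
tr_sparse_dense <- function(A, B) {
  s <- Matrix::summary(Matrix::forceSymmetric(A, uplo = "U"))
  ## forceSymmetric keeps the upper triangle; count off-diagonals twice
  w <- ifelse(s$i == s$j, 1, 2)
  sum(w * s$x * B[cbind(s$j, s$i)])
}

## Residual parameter bookkeeping ------------------------------------------

resid_pack <- function(resid) {
  switch(resid$structure,
    homogeneous = resid$par,
    diagonal = resid$par,
    unstructured = ltri_pack(resid$par)
  )
}

resid_unpack <- function(v, structure, J) {
  switch(structure,
    homogeneous = list(structure = structure, par = v[1L]),
    diagonal = list(structure = structure, par = v),
    unstructured = list(structure = structure, par = ltri_unpack(v, J))
  )
}

## Project residual parameters back into the admissible region.
resid_project <- function(resid, floor_scale) {
  fl <- 1e-10 * floor_scale
  if (resid$structure == "unstructured") {
    resid$par <- psd_floor(resid$par, scale = floor_scale)$K
    ## keep strictly PD for the Cholesky-based block inverses
    e <- eigen(resid$par, symmetric = TRUE)
    resid$par <- e$vectors %*% (pmax(e$values, fl) * t(e$vectors))
  } else {
    resid$par <- pmax(resid$par, fl)
  }
  resid
}

theta_pack <- function(covs, resid) {
  c(ltri_pack(as.matrix(covs$genetic)),
    ltri_pack(as.matrix(covs$perm)),
    ltri_pack(as.matrix(covs$plot)),
    resid_pack(resid))
}

theta_unpack <- function(v, dims, structure, J) {
  sizes <- dims * (dims + 1L) / 2L
  at <- 0L
  covs <- list()
  for (k in seq_along(dims)) {
    covs[[k]] <- ltri_unpack(v[at + seq_len(sizes[k])], dims[k])
    at <- at + sizes[k]
  }
  names(covs) <- c("genetic", "perm", "plot")
  resid <- resid_unpack(v[(at + 1L):length(v)], structure, J)
  list(covs = covs, resid = resid)
}

## Project all covariance parameters into the admissible region; returns the
## projected parameters and whether any boundary was hit.
theta_project <- function(covs, resid, floor_scale) {
  boundary <- FALSE
  for (nm in names(covs)) {
    pf <- psd_floor(as.matrix(covs[[nm]]), scale = floor_scale)
    ## strictly PD floor so K^{-1} exists
    e <- eigen(pf$K, symmetric = TRUE)
    fl <- 1e-10 * floor_scale
    covs[[nm]] <- e$vectors %*% (pmax(e$values, fl) * t(e$vectors))
    boundary <- boundary || pf$boundary || any(e$values < fl)
  }
  resid <- resid_project(structure(resid, class = "rr_residual"), floor_scale)
  list(covs = covs, resid = resid, boundary = boundary)
}

## Row-index list of a sparse matrix, for cheap per-individual submatrices.
sparse_row_list <- function(M) {
  s <- Matrix::summary(M)
  split(data.frame(j = s$j, x = s$x), factor(s$i, levels = seq_len(nrow(M))))
}

## Small quadratic form M B M' where the rows of M are given as sparse
## (index, value) lists and B is dense symmetric; avoids materializing the
## rows at full width.
row_quad_form <- function(row_list, B) {
  m <- length(row_list)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    ra <- row_list[[a]]
    for (b in seq_len(a)) {
      rb <- row_list[[b]]
      H[a, b] <- H[b, a] <-
        sum(ra$x * (B[ra$j, rb$j, drop = FALSE] %*% rb$x))
    }
  }
  H
}

## Per-effect solution blocks: BLUP coefficient matrices (c x q), the sum of
## per-unit diagonal blocks of Cinv, and (optionally) the per-unit blocks.
effect_blocks <- function(ev, pre, per_unit = FALSE) {
  out <- list()
  for (nm in names(pre$eff)) {
    e <- pre$eff[[nm]]
    u <- matrix(ev$sol[e$cols], nrow = e$c)
    colnames(u) <- e$units
    S <- NULL
    blocks <- NULL
    if (!is.null(ev$Cinv)) {
      S <- matrix(0, e$c, e$c)
      if (per_unit) blocks <- array(0, c(e$c, e$c, e$q),
                                    dimnames = list(NULL, NULL, e$units))
      for (k in seq_len(e$q)) {
        cols <- e$offset + (k - 1L) * e$c + seq_len(e$c)
        blk <- ev$Cinv[cols, cols, drop = FALSE]
        S <- S + blk
        if (per_unit) blocks[, , k] <- blk
      }
    }
    out[[nm]] <- list(u = u, S = S, blocks = blocks)
  }
  out
}

## EM updates of all covariance parameters from the current MME solution.
em_update <- function(bundle, pre, ev, covs, resid, extras) {
  eb <- effect_blocks(ev, pre)
  new_covs <- covs
  for (nm in names(pre$eff)) {
    e <- pre$eff[[nm]]
    new_covs[[nm]] <- (tcrossprod(eb[[nm]]$u) + eb[[nm]]$S) / e$q
  }
  J <- pre$J
  if (resid$structure == "homogeneous") {
    s2 <- (sum(ev$ehat^2) + tr_sparse_dense(extras$A0, ev$Cinv)) / bundle$n
    new_resid <- list(structure = "homogeneous", par = s2)
  } else if (resid$structure == "diagonal") {
    s2 <- vapply(seq_len(J), function(j) {
      rows <- pre$rows_by_harvest[[j]]
      (sum(ev$ehat[rows]^2) + tr_sparse_dense(extras$A0_h[[j]], ev$Cinv)) /
        length(rows)
    }, numeric(1))
    new_resid <- list(structure = "diagonal", par = s2)
  } else {
    Ssum <- matrix(0, J, J)
    Ncnt <- matrix(0, J, J)
    h <- bundle$harvest
    for (rows in extras$rows_by_ind) {
      hs <- h[rows]
      Ei <- tcrossprod(ev$ehat[rows]) +
        row_quad_form(extras$Trows[rows], ev$Cinv)
      Ssum[hs, hs] <- Ssum[hs, hs] + Ei
      Ncnt[hs, hs] <- Ncnt[hs, hs] + 1
    }
    Sig <- Ssum / pmax(Ncnt, 1)
    ## harvest pairs never observed together keep their previous value
    Sig[Ncnt == 0] <- resid$par[Ncnt == 0]
    new_resid <- list(structure = "unstructured", par = (Sig + t(Sig)) / 2)
  }
  list(covs = new_covs, resid = new_resid)
}

## Gradient of the restricted log-likelihood and the AI (average
## information) matrix in the packed parameter order.
ai_gradient <- function(bundle, pre, ev, covs, resid, extras) {
  n <- bundle$n
  J <- pre$J
  eb <- effect_blocks(ev, pre)
  Py <- ev$Py
  cols_F <- list()
  trs <- numeric(0)
  ## coefficient-covariance parameters
  for (nm in names(pre$eff)) {
    e <- pre$eff[[nm]]
    Ki <- ev$Kinv[[nm]]
    S <- eb[[nm]]$S
    KSK <- Ki %*% S %*% Ki
    v <- Ki %*% eb[[nm]]$u          # c x q
    pairs <- ltri_pairs(e$c)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      if (a == b) {
        tr_i <- e$q * Ki[a, a] - KSK[a, a]
        w <- matrix(0, e$c, e$q)
        w[a, ] <- v[a, ]
      } else {
        tr_i <- 2 * (e$q * Ki[a, b] - KSK[a, b])
        w <- matrix(0, e$c, e$q)
        w[a, ] <- v[b, ]
        w[b, ] <- v[a, ]
      }
      f <- as.numeric(pre$eff[[nm]]$Z %*% as.vector(w))
      cols_F[[length(cols_F) + 1L]] <- f
      trs <- c(trs, tr_i)
    }
  }
  ## residual parameters
  if (resid$structure == "homogeneous") {
    s2 <- resid$par
    tr_i <- n / s2 - tr_sparse_dense(extras$A0, ev$Cinv) / s2^2
    cols_F[[length(cols_F) + 1L]] <- Py
    trs <- c(trs, tr_i)
  } else if (resid$structure == "diagonal") {
    for (j in seq_len(J)) {
      rows <- pre$rows_by_harvest[[j]]
      s2 <- resid$par[j]
      tr_i <- length(rows) / s2 -
        tr_sparse_dense(extras$A0_h[[j]], ev$Cinv) / s2^2
      f <- numeric(n)
      f[rows] <- Py[rows]
      cols_F[[length(cols_F) + 1L]] <- f
      trs <- c(trs, tr_i)
    }
  } else {
    ## per-individual H = U_r Cinv U_r' and Rinv blocks, accumulated into
    ## the J x J pair traces
    h <- bundle$harvest
    tr_pair <- matrix(0, J, J)
    Fmat_pair <- array(0, c(n, J, J))
    ri_blocks <- extras$rinv_blocks
    for (k in seq_along(extras$rows_by_ind)) {
      rows <- extras$rows_by_ind[[k]]
      hs <- h[rows]
      m <- length(rows)
      Hi <- row_quad_form(extras$Urows[rows], ev$Cinv)
      Ri <- ri_blocks[[k]]
      for (a in seq_len(m)) {
        for (b in seq_len(a)) {
          ja <- hs[a]; jb <- hs[b]
          if (a == b) {
            tr_pair[ja, ja] <- tr_pair[ja, ja] + Ri[a, a] - Hi[a, a]
            Fmat_pair[rows[a], ja, ja] <- Fmat_pair[rows[a], ja, ja] + Py[rows[a]]
          } else {
            tr_pair[ja, jb] <- tr_pair[ja, jb] + 2 * (Ri[a, b] - Hi[a, b])
            Fmat_pair[rows[a], ja, jb] <- Fmat_pair[rows[a], ja, jb] + Py[rows[b]]
            Fmat_pair[rows[b], ja, jb] <- Fmat_pair[rows[b], ja, jb] + Py[rows[a]]
          }
        }
      }
    }
    pairs <- ltri_pairs(J)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      cols_F[[length(cols_F) + 1L]] <- Fmat_pair[, a, b]
      trs <- c(trs, tr_pair[a, b])
    }
  }
  Fm <- do.call(cbind, cols_F)
  quad <- as.numeric(crossprod(Fm, Py))
  grad <- -0.5 * (trs - quad)
  ## P F = Rinv F - U Cinv (U' F)
  UtF <- as.matrix(Matrix::crossprod(extras$U, Fm))
  PF <- as.matrix(ev$Rinv %*% Fm) - as.matrix(extras$U %*% (ev$Cinv %*% UtF))
  AI <- 0.5 * crossprod(Fm, PF)
  list(grad = grad, AI = (AI + t(AI)) / 2)
}

## One EM step from the supplied state, returning projected parameters.
em_step <- function(bundle, pre, covs, resid, floor_scale, ev = NULL) {
  if (is.null(ev)) {
    ev <- mme_eval(bundle, pre, covs, resid, want_inverse = TRUE)
    if (!ev$ok) return(NULL)
  }
  extras <- fit_extras(bundle, pre, ev, resid)
  em <- em_update(bundle, pre, ev, covs, resid, extras)
  prj <- theta_project(em$covs, em$resid, floor_scale)
  list(covs = prj$covs, resid = prj$resid, boundary = prj$boundary)
}

## Accelerated EM fallback: two EM sub-steps plus a squared-extrapolation
## candidate (SQUAREM-style), which collapses the geometric crawl EM shows
## near variance boundaries. Returns the best candidate by likelihood.
em_accel_step <- function(bundle, pre, covs, resid, floor_scale, dims,
                          structure, J, ev = NULL) {
  s1 <- em_step(bundle, pre, covs, resid, floor_scale, ev = ev)
  if (is.null(s1)) return(NULL)
  ev1 <- mme_eval(bundle, pre, s1$covs, s1$resid, want_inverse = TRUE)
  if (!ev1$ok) return(NULL)
  s2 <- em_step(bundle, pre, s1$covs, s1$resid, floor_scale, ev = ev1)
  if (is.null(s2)) {
    s1$loglik <- ev1$loglik
    return(s1)
  }
  ev2 <- mme_eval(bundle, pre, s2$covs, s2$resid, want_inverse = FALSE)
  best <- s2
  best$loglik <- if (ev2$ok) ev2$loglik else -Inf
  th0 <- theta_pack(covs, resid)
  th1 <- theta_pack(s1$covs, s1$resid)
  th2 <- theta_pack(s2$covs, s2$resid)
  r <- th1 - th0
  v <- (th2 - th1) - r
  if (sum(v^2) > 0) {
    alpha <- -sqrt(sum(r^2)) / sqrt(sum(v^2))
    alpha <- min(alpha, -1)
    th_acc <- th0 - 2 * alpha * r + alpha^2 * v
    up <- theta_unpack(th_acc, dims, structure, J)
    prj <- theta_project(up$covs, up$resid, floor_scale)
    ev_acc <- mme_eval(bundle, pre, prj$covs, prj$resid,
                       want_inverse = FALSE)
    if (ev_acc$ok && ev_acc$loglik > best$loglik) {
      best <- list(covs = prj$covs, resid = prj$resid,
                   boundary = prj$boundary, loglik = ev_acc$loglik)
    }
  }
  best
}

## Per-iteration constants that depend on the residual structure only through
## the current parameters (U changes with Rinv; the A0 crossproducts do not).
fit_extras <- function(bundle, pre, ev, resid) {
  extras <- list()
  extras$U <- ev$Rinv %*% pre$T
  if (resid$structure == "homogeneous") {
    extras$A0 <- Matrix::crossprod(pre$T)
  } else if (resid$structure == "diagonal") {
    extras$A0_h <- lapply(pre$rows_by_harvest, function(rows) {
      Matrix::crossprod(pre$T[rows, , drop = FALSE])
    })
  } else {
    extras$rows_by_ind <- split(seq_len(bundle$n), bundle$individual)
    extras$Trows <- sparse_row_list(pre$T)
    extras$Urows <- sparse_row_list(extras$U)
    ## Rinv blocks per individual, in the same order as rows_by_ind
    h <- bundle$harvest
    Sig <- resid$par
    extras$rinv_blocks <- lapply(extras$rows_by_ind, function(rows) {
      solve(Sig[h[rows], h[rows], drop = FALSE])
    })
  }
  extras
}

#' Fit the random regression model by REML
#'
#' Estimates the Kronecker-structured coefficient covariances of the genetic,
#' permanent-environment and plot random regressions and the residual
#' parameters by restricted maximum likelihood, using average-information
#' (AI) updates with step-halving and an EM fallback; pure EM and pure AI are
#' available for cross-checks. Fixed effects (BLUE), random-coefficient
#' BLUPs, and prediction-error-variance blocks for the genetic units are
#' computed at the optimum from the mixed-model equations.
#'
#' @param bundle A design from [build_design()].
#' @param init Optional named list with starting values `covs` (list
#'   `genetic`, `perm`, `plot`) and `resid` (a [residual_model()]). By
#'   default the total phenotypic variance is split equally across the four
#'   effects with diagonal coefficient covariances.
#' @param tol Convergence tolerance: relative parameter change and absolute
#'   log-likelihood change must both drop below `tol`.
#' @param max_iter Maximum number of iterations.
#' @param algorithm `"ai-em"` (AI with EM warm-up and fallback, default),
#'   `"em"` or `"ai"`.
#' @param verbose Print per-iteration progress.
#' @return An object of class `rr_fit` with elements `covs` (estimated
#'   `genetic`, `perm`, `plot` coefficient covariances), `residual`,
#'   `loglik`, `fixed_estimates`, `blup` (per-effect coefficient matrices,
#'   units in columns), `pev_genetic` (array of per-unit PEV blocks),
#'   `param_se` (asymptotic standard errors from the inverse AI matrix,
#'   where available), `converged`, `boundary`, `trace`, `n`, `rank_x`,
#'   `n_params`, `iterations`, plus the `bundle`.
#' @export
fit_reml <- function(bundle, init = NULL, tol = 1e-8, max_iter = 200L,
                     algorithm = c("ai-em", "em", "ai"), verbose = FALSE) {
  stopifnot(inherits(bundle, "rr_design"))
  algorithm <- match.arg(algorithm)
  pre <- mme_precompute(bundle)
  J <- pre$J
  vy <- stats::var(bundle$y)
  floor_scale <- vy

  dims <- vapply(pre$eff, function(e) e$c, integer(1))
  if (is.null(init)) {
    covs <- lapply(dims, function(c) diag(rep(vy / (2 * c), c), c))
    names(covs) <- names(dims)
    resid <- switch(bundle$config$residual,
      homogeneous = list(structure = "homogeneous", par = vy / 4),
      diagonal = list(structure = "diagonal", par = rep(vy / 4, J)),
      unstructured = list(structure = "unstructured",
                          par = diag(rep(vy / 4, J)))
    )
  } else {
    covs <- lapply(init$covs, as.matrix)
    resid <- list(structure = init$resid$structure, par = init$resid$par)
    stopifnot(resid$structure == bundle$config$residual)
  }
  pr <- theta_project(covs, resid, floor_scale)
  covs <- pr$covs; resid <- pr$resid
  boundary_hit <- pr$boundary

  ev <- mme_eval(bundle, pre, covs, resid, want_inverse = TRUE)
  if (!ev$ok) stop("starting values yield a singular system", call. = FALSE)
  loglik <- ev$loglik
  trace <- data.frame(iter = 0L, loglik = loglik, step = "init",
                      delta = NA_real_, stringsAsFactors = FALSE)
  n_warmup <- if (algorithm == "ai-em") 2L else 0L
  converged <- FALSE
  last_AI <- NULL
  iter <- 0L

  ai_cooldown <- 0L
  for (iter in seq_len(max_iter)) {
    theta_old <- theta_pack(covs, resid)
    use_em <- algorithm == "em" || iter <= n_warmup || ai_cooldown > 0L
    if (ai_cooldown > 0L) ai_cooldown <- ai_cooldown - 1L
    step_type <- "em"
    cand <- NULL

    if (!use_em) {
      extras <- fit_extras(bundle, pre, ev, resid)
      ag <- tryCatch(ai_gradient(bundle, pre, ev, covs, resid, extras),
                     error = function(e) NULL)
      if (!is.null(ag)) {
        last_AI <- ag
        step <- tryCatch(
          solve(ag$AI + diag(1e-8 * max(diag(ag$AI)), nrow(ag$AI)), ag$grad),
          error = function(e) NULL)
        if (!is.null(step)) {
          ## trust region: an unchecked early AI step can jump between
          ## likelihood basins even while ascending
          cap <- 5 * (sqrt(sum(theta_old^2)) + 1e-8)
          nrm <- sqrt(sum(step^2))
          if (nrm > cap) step <- step * (cap / nrm)
          halve <- 0L
          repeat {
            th_new <- theta_old + step
            up <- theta_unpack(th_new, dims, resid$structure, J)
            prj <- theta_project(up$covs, up$resid, floor_scale)
            ev_new <- mme_eval(bundle, pre, prj$covs, prj$resid,
                               want_inverse = FALSE)
            if (ev_new$ok && ev_new$loglik >= loglik - 1e-10) {
              cand <- list(covs = prj$covs, resid = prj$resid,
                           boundary = prj$boundary)
              step_type <- if (halve > 0L) sprintf("ai/%d", halve) else "ai"
              break
            }
            halve <- halve + 1L
            if (halve > 8L) break
            step <- step / 2
          }
        }
      }
      if (is.null(cand)) {
        if (algorithm == "ai") {
          stop("AI step failed to improve the likelihood; ",
               "use algorithm = 'ai-em'", call. = FALSE)
        }
        ## a failed AI step usually means a boundary region where it will
        ## keep failing; rest it for a few iterations
        ai_cooldown <- 3L
      }
    }
    if (is.null(cand)) {
      if (algorithm == "em" || iter <= n_warmup) {
        cand <- em_step(bundle, pre, covs, resid, floor_scale, ev = ev)
      } else {
        ## accelerated EM fallback; accept only if it does not decrease the
        ## likelihood (the unstructured-residual update is only
        ## approximately monotone under missing records) — otherwise no
        ## improving direction exists and the point is stationary
        cand <- em_accel_step(bundle, pre, covs, resid, floor_scale, dims,
                              resid$structure, J, ev = ev)
        if (!is.null(cand) && !is.null(cand$loglik) &&
            cand$loglik < loglik - 1e-10) {
          cand <- NULL
        }
        step_type <- "em+"
      }
      if (is.null(cand)) {
        converged <- TRUE
        trace <- rbind(trace, data.frame(iter = iter, loglik = loglik,
                                         step = "stall", delta = 0,
                                         stringsAsFactors = FALSE))
        break
      }
    }

    covs <- cand$covs
    resid <- cand$resid
    boundary_hit <- boundary_hit || cand$boundary
    ev <- mme_eval(bundle, pre, covs, resid, want_inverse = TRUE)
    if (!ev$ok) stop("iteration produced a singular system", call. = FALSE)
    d_loglik <- ev$loglik - loglik
    loglik <- ev$loglik
    theta_new <- theta_pack(covs, resid)
    d_par <- sqrt(sum((theta_new - theta_old)^2)) /
      (sqrt(sum(theta_old^2)) + 1e-10)
    trace <- rbind(trace, data.frame(iter = iter, loglik = loglik,
                                     step = step_type, delta = d_par,
                                     stringsAsFactors = FALSE))
    if (verbose) {
      message(sprintf("iter %3d  logL %.6f  step %-6s  dpar %.3e", iter,
                      loglik, step_type, d_par))
    }
    if (iter > n_warmup && d_par < tol && abs(d_loglik) < tol) {
      converged <- TRUE
      break
    }
  }

  ## final solution with per-unit PEV blocks for the genetic effect
  eb <- effect_blocks(ev, pre, per_unit = TRUE)
  blue <- stats::setNames(ev$sol[seq_len(pre$px)], colnames(bundle$X))
  blup <- lapply(eb, function(x) x$u)
  pev_genetic <- eb$genetic$blocks

  param_se <- NULL
  if (!is.null(last_AI)) {
    se <- tryCatch(sqrt(pmax(diag(solve(last_AI$AI)), 0)),
                   error = function(e) NULL)
    if (!is.null(se)) {
      param_se <- data.frame(parameter = theta_names(dims, resid$structure, J),
                             estimate = theta_pack(covs, resid), se = se,
                             stringsAsFactors = FALSE)
    }
  }

  structure(
    list(covs = covs,
         residual = structure(resid, class = "rr_residual"),
         loglik = loglik,
         fixed_estimates = blue,
         blup = blup,
         pev_genetic = pev_genetic,
         param_se = param_se,
         converged = converged,
         boundary = boundary_hit,
         trace = trace,
         iterations = iter,
         n = bundle$n,
         rank_x = pre$px,
         n_params = count_parameters(bundle$config,
                                     length(bundle$timeline$years)),
         bundle = bundle),
    class = "rr_fit"
  )
}

theta_names <- function(dims, structure, J) {
  nms <- character(0)
  for (nm in names(dims)) {
    pairs <- ltri_pairs(dims[[nm]])
    nms <- c(nms, sprintf("K_%s[%d,%d]", nm, pairs[, 1L] - 1L,
                          pairs[, 2L] - 1L))
  }
  res <- switch(structure,
    homogeneous = "sigma2_res",
    diagonal = sprintf("sigma2_res[%d]", seq_len(J)),
    unstructured = {
      pairs <- ltri_pairs(J)
      sprintf("Sigma_res[%d,%d]", pairs[, 1L], pairs[, 2L])
    })
  c(nms, res)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf(
    "<rr_fit> logL = %.4f, %d iterations, %s (%d parameters)\n",
    x$loglik, x$iterations,
    if (x$converged) "converged" else "NOT converged", x$n_params))
  cat("  genetic coefficient covariance:\n")
  print(signif(x$covs$genetic, 4))
  invisible(x)
}

#' Solve the mixed-model equations at fixed covariance parameters
#'
#' Builds and solves the Henderson system for the supplied coefficient
#' covariances and residual model, returning BLUEs, BLUPs and the
#' prediction-error-variance blocks of the genetic units read from the
#' corresponding diagonal blocks of the inverse coefficient matrix.
#'
#' @inheritParams reml_loglik
#' @return List with `blue`, `blup` (per-effect coefficient matrices, one
#'   column per unit), `pev_genetic` (array, one slice per genetic unit),
#'   `loglik`, and `relative_residual` (the relative norm of the MME
#'   residual at the returned solution).
#' @export
solve_mme <- function(bundle, covs, resid) {
  stopifnot(inherits(bundle, "rr_design"), inherits(resid, "rr_residual"))
  pre <- mme_precompute(bundle)
  ev <- mme_eval(bundle, pre, covs, resid, want_inverse = TRUE)
  if (!ev$ok) stop("coefficient matrix not positive definite", call. = FALSE)
  eb <- effect_blocks(ev, pre, per_unit = TRUE)
  ## residual of the linear system, reconstructed through the Cholesky factor
  Csol <- crossprod(ev$cholC, ev$cholC %*% ev$sol)
  rel <- sqrt(sum((as.numeric(Csol) - ev$rhs)^2)) / sqrt(sum(ev$rhs^2))
  list(
    blue = stats::setNames(ev$sol[seq_len(pre$px)], colnames(bundle$X)),
    blup = lapply(eb, function(x) x$u),
    pev_genetic = eb$genetic$blocks,
    loglik = ev$loglik,
    relative_residual = rel
  )
}
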