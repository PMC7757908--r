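## Internal numerical helpers.

## Symmetrize and floor eigenvalues so a coefficient covariance stays inside
## the PSD cone. The floor is relative to the matrix trace with a tiny
## absolute fallback scaled to the data variance handed in via `scale`.
psd_floor <- function(K, scale = 1, rel = 1e-10) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  floor_val <- max(rel * sum(pmax(diag(K), 0)), 1e-12 * scale)
  hit <- e$values < floor_val
  if (!any(hit)) return(list(K = K, boundary = FALSE))
  v <- pmax(e$values, floor_val)
  list(K = e$vectors %*% (v * t(e$vectors)), boundary = TRUE)
}

## Draw n rows from N(0, K) via the (pivoted-safe) Cholesky of K.
rmvn <- function(n, K) {
  K <- as.matrix(K)
  p <- ncol(K)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  matrix(stats::rnorm(n * p), n, p) %*% t(L)
}

## Lower-triangle packing of a symmetric matrix (column-major over the
## lower triangle), and its inverse.
ltri_pack <- function(K) K[lower.tri(K, diag = TRUE)]

ltri_unpack <- function(v, p) {
  K <- matrix(0, p, p)
  K[lower.tri(K, diag = TRUE)] <- v
  K + t(K) - diag(diag(K), p)
}

## Index pairs (row >= col) matching ltri_pack order.
ltri_pairs <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

## Derive a reproducible sub-seed from a master seed, kept inside 32-bit
## integer range.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
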