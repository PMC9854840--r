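# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never clobber user randomness.
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Draw n rows from N(0, Sigma); eigen-based so PSD-singular Sigma is fine.
rmvn_ <- function(n, sigma) {
  t <- nrow(sigma)
  if (t == 0L) return(matrix(0, n, 0L))
  ee <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  z <- matrix(stats::rnorm(n * t), n, t)
  z %*% (t(ee$vectors) * sqrt(lam))
}

is_symmetric_ <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Symmetrize and check positive semidefiniteness within tolerance.
check_psd_ <- function(m, tol = 1e-8, label = "matrix") {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3e)",
                 label, min(ev)), call. = FALSE)
  m
}

# Moore-Penrose pseudoinverse by SVD with a relative singular-value cutoff.
pinv_ <- function(m, rtol = 1e-10) {
  sv <- svd(m)
  pos <- sv$d > rtol * max(sv$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Fix eigenvector sign so the largest-magnitude element is positive.
fix_sign_ <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
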