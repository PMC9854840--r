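# Independent oracles used to cross-check the implementation. Each is
# written from the definition, without reusing the package's internals.

# Brute-force Procrustes superimposition for a handful of configurations:
# centre and scale each to unit centroid size, then minimize the summed
# squared distances to the mean shape over per-specimen rotation angles by
# a dense grid (the first specimen's angle fixed at zero) followed by
# Nelder-Mead refinement.
oracle_gpa <- function(mats) {
  n <- length(mats)
  pre <- lapply(mats, function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  })
  rotmat <- function(th) cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  objective <- function(angles) {
    rot <- lapply(seq_len(n), function(i)
      pre[[i]] %*% rotmat(c(0, angles)[i]))
    cons <- Reduce(`+`, rot) / n
    sum(vapply(rot, function(r) sum((r - cons)^2), 0))
  }
  grid <- seq(0, 2 * pi, length.out = 73L)[-73L]
  combos <- as.matrix(expand.grid(rep(list(grid), n - 1L)))
  vals <- apply(combos, 1L, objective)
  best <- combos[which.min(vals), ]
  opt <- stats::optim(best, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000L))
  angles <- c(0, opt$par)
  rot <- lapply(seq_len(n), function(i) pre[[i]] %*% rotmat(angles[i]))
  cons <- Reduce(`+`, rot) / n
  list(shapes = rot, consensus = cons, rss = opt$value)
}

# Gene-dropping estimate of the additive relationship matrix: drop unique
# founder alleles down the pedigree n_drops times; relationship = twice
# the mean fraction of allele draws identical by descent. Returns the
# estimate and its Monte-Carlo standard error per entry.
oracle_gene_drop <- function(ped, n_drops = 200000L, seed = 1L) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  set.seed(seed)
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  next_allele <- 0L
  for (i in idx) {
    d <- ped$dam[i]; s <- ped$sire[i]
    if (is.na(d)) {
      al1[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, idx[d]], al2[, idx[d]])
    }
    if (is.na(s)) {
      al2[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, idx[s]], al2[, idx[s]])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  A_se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) for (j in idx[idx >= i]) {
    kin <- ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
              (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
    A_hat[i, j] <- A_hat[j, i] <- 2 * mean(kin)
    A_se[i, j] <- A_se[j, i] <- 2 * stats::sd(kin) / sqrt(n_drops)
  }
  list(A = A_hat, se = A_se)
}

# Dense GLS restricted log-likelihood from the textbook formula
# -1/2 [log|V| + log|X'V^-1 X| + y'Py], built with kronecker(), solve()
# and determinant() only.
oracle_restricted_logl <- function(Y, log_cs, A, dam, sire, G, Mat, Pat,
                                   R) {
  n <- nrow(Y); t <- ncol(Y)
  Zh <- function(f) {
    f <- factor(f)
    Z <- matrix(0, n, nlevels(f))
    Z[cbind(which(!is.na(f)), as.integer(f)[!is.na(f)])] <- 1
    Z
  }
  Zm <- Zh(dam); Zp <- Zh(sire)
  V <- kronecker(G, A) + kronecker(Mat, Zm %*% t(Zm)) +
    kronecker(Pat, Zp %*% t(Zp)) + kronecker(R, diag(n))
  X0 <- cbind(1, log_cs - mean(log_cs))
  X <- kronecker(diag(t), X0)
  y <- as.vector(Y)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, t(X) %*% Vi %*% y)
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus + sum(y * Py)))
}

# Expectation-of-mean-squares estimator for the balanced one-way random
# (half-sib) design: sigma2_between = (MSB - MSW) / m.
oracle_halfsib_anova <- function(y, group) {
  group <- factor(group)
  m <- unique(table(group))
  stopifnot(length(m) == 1L)
  gm <- tapply(y, group, mean)
  msb <- m * sum((gm - mean(y))^2) / (nlevels(group) - 1L)
  msw <- sum((y - gm[group])^2) / (length(y) - nlevels(group))
  c(between = (msb - msw) / m, within = msw)
}

# Roots of the characteristic polynomial of a 2 x 2 matrix.
oracle_eigen_2x2 <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- sqrt(tr^2 / 4 - dt)
  sort(c(tr / 2 + disc, tr / 2 - disc), decreasing = TRUE)
}

# Random symmetric PSD matrix.
random_psd <- function(t, seed) {
  set.seed(seed)
  L <- matrix(rnorm(t * t), t)
  crossprod(L) + diag(0.1, t)
}

# Random non-degenerate configurations under a scheme-compatible template.
random_configs <- function(n, seed, noise = 0.01) {
  tm <- viper_head_template()
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(id = paste0("R", i),
         coords = tm + matrix(rnorm(length(tm), 0, noise), nrow(tm)),
         metadata = list()))
}
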