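# Generalized Procrustes superimposition with optional bending-energy
# sliding of semilandmarks.
#
# Internal coordinate convention: a configuration of k landmarks is
# flattened to a 2k-vector c(x_1..x_k, y_1..y_k). Aligned samples are
# stored as an n x 2k matrix.

flatten_ <- function(m) c(m[, 1L], m[, 2L])

unflatten_ <- function(v) {
  k <- length(v) / 2L
  cbind(v[seq_len(k)], v[k + seq_len(k)])
}

config_coords_ <- function(x) {
  if (is.list(x) && !is.null(x$coords)) x$coords else as.matrix(x)
}

# Coerce a list of configurations (or k x 2 x n array) to an array.
config_array_ <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) return(configs)
  mats <- lapply(configs, config_coords_)
  k <- nrow(mats[[1L]])
  arr <- array(NA_real_, c(k, 2L, length(mats)))
  for (i in seq_along(mats)) {
    if (!all(dim(mats[[i]]) == c(k, 2L)))
      stop(sprintf("configuration %d: dimensions differ from the first", i),
           call. = FALSE)
    arr[, , i] <- mats[[i]]
  }
  if (!all(is.finite(arr))) stop("non-finite landmark coordinates",
                                 call. = FALSE)
  arr
}

config_ids_ <- function(configs, n) {
  if (is.array(configs)) {
    dn <- dimnames(configs)[[3L]]
    if (!is.null(dn)) return(dn)
    return(as.character(seq_len(n)))
  }
  ids <- vapply(seq_along(configs), function(i)
    as.character(configs[[i]]$id %||% i), "")
  ids
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid: the standard geometric-morphometric size measure. It is
#' invariant to translation and rotation and scales linearly with the
#' configuration.
#'
#' @param config A configuration (list with `coords`) or a k x 2 matrix.
#' @return A positive scalar.
#' @export
centroid_size <- function(config) {
  m <- config_coords_(config)
  if (nrow(m) < 2L) stop("need at least 2 landmarks", call. = FALSE)
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs <= .Machine$double.eps * max(1, max(abs(m))) * nrow(m))
    stop("degenerate configuration: all landmarks coincide (zero centroid size)",
         call. = FALSE)
  cs
}

# Optimal rotation R (det +1) minimizing |X R - C|_F for k x 2 matrices.
rot_fit_ <- function(X, C) {
  sv <- svd(crossprod(X, C))
  d <- det(sv$u) * det(sv$v)
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

# Thin-plate-spline bending-energy matrix (k x k) for a 2-D reference.
bending_energy_matrix_ <- function(ref) {
  k <- nrow(ref)
  r2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(r2 > 0, r2 * log(r2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Li <- solve(L)
  Be <- Li[seq_len(k), seq_len(k), drop = FALSE]
  (Be + t(Be)) / 2
}

# Slide semilandmarks of one configuration along the chord between their
# scheme neighbours so as to minimize bending energy against `ref`.
slide_one_ <- function(X, ref, Be, scheme) {
  sl <- scheme$semilandmarks
  s <- sl[, 1L]
  U <- X[sl[, 3L], , drop = FALSE] - X[sl[, 2L], , drop = FALSE]
  len <- sqrt(rowSums(U^2))
  if (any(len < 1e-12))
    stop("degenerate semilandmark chord (coincident neighbours)",
         call. = FALSE)
  U <- U / len
  v <- X - ref
  Lrow <- Be[s, , drop = FALSE]
  rhs <- U[, 1L] * (Lrow %*% v[, 1L]) + U[, 2L] * (Lrow %*% v[, 2L])
  M <- Be[s, s, drop = FALSE] * tcrossprod(U)
  tt <- tryCatch(solve(M, rhs),
                 error = function(e)
                   solve(M + diag(1e-10 * max(abs(diag(M))), nrow(M)), rhs))
  X[s, ] <- X[s, ] - as.vector(tt) * U
  X
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of landmark configurations: each configuration
#' is centred, scaled to unit centroid size, and rotated to the current
#' consensus (orthogonal Procrustes fit via the cross-covariance SVD); the
#' consensus is then recomputed and the loop repeats until its
#' root-mean-square change falls below `tol`. With `slide = TRUE`,
#' semilandmarks declared in the scheme are additionally slid along the
#' chord between their neighbours to minimize thin-plate-spline bending
#' energy against the consensus, alternating sliding and re-superimposition.
#'
#' @param configs List of configurations (as from [read_tps()]) or a
#'   k x 2 x n array.
#' @param scheme A [landmark_scheme()]; required when `slide = TRUE`.
#' @param slide Logical; slide semilandmarks by minimizing bending energy.
#' @param proj Logical; orthogonally project the aligned coordinates onto
#'   the tangent space at the consensus. Off by default so that every
#'   aligned configuration keeps exactly unit centroid size; turn on (or use
#'   [symmetric_component()], which projects by default) before linear
#'   multivariate analysis.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum alignment iterations per cycle.
#' @param slide_cycles Maximum outer slide/re-align cycles.
#' @param slide_tol Stop sliding when the RMS coordinate change of a cycle
#'   falls below this.
#' @return An object of class `aligned_shapes`: list with `shapes`
#'   (n x 2k matrix, columns x1..xk then y1..yk), `centroid_sizes`
#'   (original units), `consensus` (2k vector), `ids`, `k`, and the
#'   per-iteration residual sum of squares as attribute `rss`.
#' @export
gpa <- function(configs, scheme = NULL, slide = FALSE, proj = FALSE,
                tol = 1e-10, max_iter = 100L, slide_cycles = 5L,
                slide_tol = 1e-8) {
  arr <- config_array_(configs)
  n <- dim(arr)[3L]
  k <- dim(arr)[1L]
  if (n < 2L) stop("need at least 2 configurations", call. = FALSE)
  if (slide) {
    if (is.null(scheme)) stop("slide = TRUE requires a scheme", call. = FALSE)
    if (nrow(scheme$semilandmarks) == 0L) slide <- FALSE
  }
  if (!is.null(scheme) && k != scheme$n_landmarks)
    stop(sprintf("configurations have %d landmarks but scheme declares %d",
                 k, scheme$n_landmarks), call. = FALSE)

  cs <- numeric(n)
  for (i in seq_len(n)) {
    cs[i] <- centroid_size(arr[, , i])
    arr[, , i] <- scale(arr[, , i], scale = FALSE) / cs[i]
  }

  rss <- numeric(0)
  align_ <- function(arr) {
    cons <- arr[, , 1L]
    cons <- cons / sqrt(sum(cons^2))
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% rot_fit_(arr[, , i], cons)
      new_cons <- apply(arr, c(1L, 2L), mean)
      rss[length(rss) + 1L] <<-
        sum(sweep(arr, c(1L, 2L), new_cons)^2)
      new_cons_u <- new_cons / sqrt(sum(new_cons^2))
      delta <- sqrt(mean((new_cons_u - cons)^2))
      cons <- new_cons_u
      if (delta < tol) return(list(arr = arr, cons = cons))
    }
    stop(sprintf("GPA did not converge in %d iterations (last delta %.3e)",
                 max_iter, delta), call. = FALSE)
  }

  fit <- align_(arr)
  if (slide) {
    for (cycle in seq_len(slide_cycles)) {
      Be <- bending_energy_matrix_(fit$cons)
      old <- fit$arr
      for (i in seq_len(n)) {
        Xs <- slide_one_(fit$arr[, , i], fit$cons, Be, scheme)
        Xs <- scale(Xs, scale = FALSE)
        fit$arr[, , i] <- Xs / sqrt(sum(Xs^2))
      }
      fit <- align_(fit$arr)
      if (sqrt(mean((fit$arr - old)^2)) < slide_tol) break
    }
  }

  shapes <- t(apply(fit$arr, 3L, flatten_))
  consensus <- flatten_(fit$cons)
  if (proj) shapes <- tangent_project_(shapes, consensus)
  structure(list(shapes = shapes, centroid_sizes = cs,
                 consensus = consensus, ids = config_ids_(configs, n),
                 k = k, proj = proj),
            class = "aligned_shapes", rss = rss)
}

# Orthogonal projection of unit-size pre-shapes onto the tangent plane at
# the (unit-size) consensus: x -> x - (x.c)c + c.
tangent_project_ <- function(shapes, consensus) {
  cu <- consensus / sqrt(sum(consensus^2))
  proj <- shapes - (shapes %*% cu) %*% t(cu)
  sweep(proj, 2L, cu, `+`)
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("Procrustes-aligned shapes: %d specimens, %d landmarks%s\n",
              nrow(x$shapes), x$k,
              if (isTRUE(x$proj)) " (tangent-projected)" else ""))
  cat(sprintf("Centroid size: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$centroid_sizes), min(x$centroid_sizes),
              max(x$centroid_sizes)))
  invisible(x)
}

# n x 2k shape matrix back to a k x 2 x n array.
shapes_array_ <- function(aligned) {
  n <- nrow(aligned$shapes)
  arr <- array(NA_real_, c(aligned$k, 2L, n),
               dimnames = list(NULL, NULL, aligned$ids))
  for (i in seq_len(n)) arr[, , i] <- unflatten_(aligned$shapes[i, ])
  arr
}
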