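# Object-symmetry (reflect - relabel - average) extraction of the
# symmetric shape component.

# Reflect a k x 2 configuration across the y axis and swap left/right labels.
reflect_relabel_ <- function(X, swap) {
  Xr <- X
  Xr[, 1L] <- -Xr[, 1L]
  Xr[swap, , drop = FALSE]
}

# Rotation (det +1) aligning the midline principal axis of a symmetric
# consensus with the y axis; of the two axis orientations, the one keeping
# the configuration closest to `prev` (if given) is chosen.
midline_rotation_ <- function(cons, midline, prev = NULL) {
  M <- cons[midline, , drop = FALSE]
  S <- crossprod(M)
  v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
  rot_for_ <- function(v) cbind(c(v[2L], -v[1L]), v)  # maps v -> (0, 1)
  R1 <- rot_for_(v)
  R2 <- rot_for_(-v)
  if (is.null(prev)) {
    if (sum((cons %*% R1 - cons)^2) <= sum((cons %*% R2 - cons)^2)) R1 else R2
  } else {
    if (sum((cons %*% R1 - prev)^2) <= sum((cons %*% R2 - prev)^2)) R1 else R2
  }
}

# GPA loop whose consensus is forced to exact bilateral symmetry and
# midline-on-y-axis orientation each iteration. With such a consensus the
# optimal rotation of a configuration and of its reflected-relabelled copy
# commute, so averaged shapes come out exactly symmetric.
sym_align_ <- function(arr, scheme, tol = 1e-12, max_iter = 200L) {
  n <- dim(arr)[3L]
  swap <- scheme_swap_(scheme)
  symmetrize_ <- function(C, prev = NULL) {
    C <- (C + reflect_relabel_(C, swap)) / 2
    R <- midline_rotation_(C, scheme$midline, prev)
    C <- C %*% R
    C / sqrt(sum(C^2))
  }
  cons <- symmetrize_(apply(arr, c(1L, 2L), mean))
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% rot_fit_(arr[, , i], cons)
    new_cons <- symmetrize_(apply(arr, c(1L, 2L), mean), prev = cons)
    delta <- sqrt(mean((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
  }
  list(arr = arr, cons = cons)
}

#' Symmetric component of aligned shapes
#'
#' Removes asymmetric variation from configurations of a bilaterally
#' symmetric structure (object symmetry): each specimen is paired with its
#' reflected copy with left/right labels swapped according to the scheme;
#' originals and reflected copies are superimposed together against a
#' consensus constrained to exact bilateral symmetry with the midline on
#' the second coordinate axis; each specimen's symmetric shape is the
#' average of its two aligned copies. The averages are re-superimposed and,
#' by default, projected onto the tangent space at the consensus. Output
#' shapes are exactly mirror-symmetric: paired landmarks coincide with the
#' mirror image of their counterparts and midline landmarks have zero
#' first coordinate.
#'
#' @param aligned An [gpa()] result (`aligned_shapes`).
#' @param scheme A [landmark_scheme()] declaring pairs and midline.
#' @param proj Logical; project onto the tangent space at the consensus
#'   (default `TRUE`). The symmetric shape space of a scheme with p pairs
#'   and m midline landmarks then has dimension 2p + m - 2.
#' @return An `aligned_shapes` object of symmetric shapes (original
#'   centroid sizes are carried over).
#' @export
symmetric_component <- function(aligned, scheme, proj = TRUE) {
  if (!inherits(aligned, "aligned_shapes"))
    stop("`aligned` must be a gpa() result", call. = FALSE)
  if (nrow(scheme$pairs) == 0L)
    stop("scheme declares no bilateral pairs; object symmetry undefined",
         call. = FALSE)
  if (aligned$k != scheme$n_landmarks)
    stop("scheme does not match the number of landmarks", call. = FALSE)
  arr <- shapes_array_(aligned)
  n <- dim(arr)[3L]
  swap <- scheme_swap_(scheme)

  # doubled sample: originals then reflected-relabelled copies
  arr2 <- array(NA_real_, c(aligned$k, 2L, 2L * n))
  arr2[, , seq_len(n)] <- arr
  for (i in seq_len(n))
    arr2[, , n + i] <- reflect_relabel_(arr[, , i], swap)

  fit <- sym_align_(arr2, scheme)
  sym <- array(NA_real_, c(aligned$k, 2L, n))
  for (i in seq_len(n)) {
    S <- (fit$arr[, , i] + reflect_relabel_(fit$arr[, , n + i], swap)) / 2
    # enforce exact mirror symmetry (removes residual numerical asymmetry)
    S <- (S + reflect_relabel_(S, swap)) / 2
    S <- scale(S, scale = FALSE)
    sym[, , i] <- S / sqrt(sum(S^2))
  }

  refit <- sym_align_(sym, scheme)
  shapes <- t(apply(refit$arr, 3L, flatten_))
  consensus <- flatten_(refit$cons)
  if (proj) shapes <- tangent_project_(shapes, consensus)
  structure(list(shapes = shapes, centroid_sizes = aligned$centroid_sizes,
                 consensus = consensus, ids = aligned$ids, k = aligned$k,
                 proj = proj),
            class = "aligned_shapes")
}
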