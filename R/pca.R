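#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the sample covariance matrix of the aligned
#' (optionally symmetrized) Procrustes coordinates. Scores of the leading
#' components are the shape variables passed to the quantitative-genetic
#' model. Loading signs are fixed so each column's largest-magnitude
#' element is positive.
#'
#' @param aligned An `aligned_shapes` object.
#' @param n_retained Number of components to retain (default: all with
#'   positive eigenvalues). Must not exceed the count of positive
#'   eigenvalues.
#' @param positive_tol Relative threshold below which eigenvalues are
#'   treated as zero.
#' @return An object of class `shape_pca`: `eigenvalues` (all, descending),
#'   `loadings` (2k x n_retained, orthonormal), `scores`
#'   (n x n_retained, centred), `consensus`, `center` (mean shape),
#'   `cumulative` (fractions of total variance), `n_positive`, `ids`.
#' @export
shape_pca <- function(aligned, n_retained = NULL, positive_tol = 1e-10) {
  X <- aligned$shapes
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 specimens", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  lam <- sv$d^2 / (n - 1)
  n_pos <- sum(lam > positive_tol * max(lam))
  if (is.null(n_retained)) n_retained <- n_pos
  if (n_retained > n_pos)
    stop(sprintf(
      "n_retained = %d exceeds the number of positive eigenvalues (rank %d)",
      n_retained, n_pos), call. = FALSE)
  if (n_retained < 1L) stop("n_retained must be >= 1", call. = FALSE)
  load <- sv$v[, seq_len(n_retained), drop = FALSE]
  for (j in seq_len(n_retained)) load[, j] <- fix_sign_(load[, j])
  scores <- Xc %*% load
  structure(list(
    eigenvalues = lam,
    loadings = load,
    scores = scores,
    consensus = aligned$consensus,
    center = ctr,
    cumulative = cumsum(lam) / sum(lam),
    n_positive = n_pos,
    n_retained = n_retained,
    ids = aligned$ids), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d specimens, %d positive eigenvalues, %d retained\n",
              nrow(x$scores), x$n_positive, x$n_retained))
  show <- seq_len(min(x$n_retained, 8L))
  tab <- data.frame(
    PC = show,
    eigenvalue = signif(x$eigenvalues[show], 5),
    proportion = round(x$eigenvalues[show] / sum(x$eigenvalues), 4),
    cumulative = round(x$cumulative[show], 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarize a shape PCA as a table
#'
#' @param object A [shape_pca()] result.
#' @param ... Unused.
#' @return Data frame with eigenvalue, proportion and cumulative proportion
#'   per component (all components, down to the rank).
#' @export
summary.shape_pca <- function(object, ...) {
  lam <- object$eigenvalues
  data.frame(PC = seq_along(lam), eigenvalue = lam,
             proportion = lam / sum(lam),
             cumulative = object$cumulative)
}

#' Back-project a trait-space vector to a landmark displacement field
#'
#' Maps a vector expressed in the retained principal-component basis (for
#' example an eigenvector of the heritability matrix, or a predicted
#' selection response) back to landmark space as a displacement field about
#' the consensus shape. Because the loadings are orthonormal the norm is
#' preserved.
#'
#' @param vector Numeric vector of length `n_retained`.
#' @param space A [shape_pca()] result.
#' @return A 2k-vector of landmark displacements (x-block then y-block);
#'   reshape with two columns to plot arrows at the consensus.
#' @export
back_project <- function(vector, space) {
  if (length(vector) != space$n_retained)
    stop(sprintf("vector has length %d but %d components are retained",
                 length(vector), space$n_retained), call. = FALSE)
  drop(space$loadings %*% vector)
}
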