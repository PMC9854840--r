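# Multivariate heritability summaries from fitted variance components.

#' Trace proportions of the phenotypic covariance
#'
#' The fraction of the total phenotypic variance (trace of
#' P = G + Mat + Pat + R) captured by each component matrix.
#'
#' @param vc A `variance_components` object (or any list with matrices
#'   `G`, `Mat`, `Pat`, `R`).
#' @return Named numeric vector (`G`, `Mat`, `Pat`, `R`) summing to 1.
#' @export
variance_proportions <- function(vc) {
  tr <- vapply(vc[c("G", "Mat", "Pat", "R")],
               function(m) sum(diag(m)), 0)
  tot <- sum(tr)
  if (tot <= 0) stop("trace of P is not positive", call. = FALSE)
  tr / tot
}

#' Multivariate heritability matrix G P^-
#'
#' The numerator covariance matrix multiplied by the Moore-Penrose
#' generalized inverse of the phenotypic covariance matrix. With the
#' additive-genetic matrix as numerator this is the multivariate analogue
#' of heritability entering the generalized breeders' equation
#' `delta_zbar = G P^- S`; with the maternal matrix it quantifies maternal
#' determination (Mat P^-).
#'
#' @param numerator Symmetric t x t matrix (G or Mat).
#' @param P Symmetric positive-semidefinite t x t phenotypic matrix.
#' @param rtol Relative singular-value cutoff for the pseudoinverse.
#' @return The t x t product matrix (generally non-symmetric).
#' @export
gp_minus <- function(numerator, P, rtol = 1e-10) {
  if (!is_symmetric_(numerator))
    stop("numerator matrix is not symmetric", call. = FALSE)
  if (!is_symmetric_(P)) stop("P is not symmetric", call. = FALSE)
  check_psd_(P, label = "P")
  numerator %*% pinv_((P + t(P)) / 2, rtol = rtol)
}

#' Eigen-summary of a (possibly non-symmetric) trait-space matrix
#'
#' Eigenvalues sorted descending by real part, unit-norm eigenvectors with
#' sign fixed so the largest-magnitude element is positive, and cumulative
#' fractions of the positive spectrum. Products such as G P^- are similar
#' to a symmetric PSD matrix whenever the components are valid, so
#' eigenvalues must be real; a non-negligible imaginary part signals
#' invalid component matrices and raises an error.
#'
#' @param M Square numeric matrix.
#' @param imag_tol Tolerance on the relative imaginary magnitude.
#' @return List with `values`, `vectors` (columns), `cumulative`
#'   (fractions of the positive spectrum), and `cumulative_trace`
#'   (fractions of the full trace).
#' @export
eigen_summary <- function(M, imag_tol = 1e-8) {
  ee <- eigen(M)
  scale <- max(1, max(Mod(ee$values)))
  if (max(abs(Im(ee$values))) >= imag_tol * scale)
    stop(sprintf("eigenvalues have imaginary magnitude %.3e; component matrices are invalid",
                 max(abs(Im(ee$values)))), call. = FALSE)
  vals <- Re(ee$values)
  vecs <- Re(ee$vectors)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    vecs[, j] <- vecs[, j] / sqrt(sum(vecs[, j]^2))
    vecs[, j] <- fix_sign_(vecs[, j])
  }
  pos <- pmax(vals, 0)
  list(values = vals, vectors = vecs,
       cumulative = if (sum(pos) > 0) cumsum(pos) / sum(pos) else pos,
       cumulative_trace = if (sum(vals) != 0) cumsum(vals) / sum(vals)
                          else vals)
}

#' Angle between two trait-space directions
#'
#' `acos(|v1 . v2| / (|v1| |v2|))` in degrees. The absolute dot product
#' makes the angle independent of eigenvector sign, so results lie in
#' [0, 90].
#'
#' @param v1,v2 Nonzero numeric vectors of equal length.
#' @return Angle in degrees.
#' @export
vector_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction", call. = FALSE)
  if (length(v1) != length(v2)) stop("vector lengths differ", call. = FALSE)
  acos(min(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

#' Predicted selection response (generalized breeders' equation)
#'
#' `delta_zbar = (G P^-) S`: the expected between-generation change of the
#' trait mean under a selection differential S.
#'
#' @param GPm The heritability matrix from [gp_minus()].
#' @param S Numeric selection differential (trait units).
#' @return List with `S` and `delta_z`.
#' @export
predict_response <- function(GPm, S) {
  if (length(S) != ncol(GPm))
    stop(sprintf("S has length %d but GP- is %d x %d",
                 length(S), nrow(GPm), ncol(GPm)), call. = FALSE)
  list(S = as.numeric(S), delta_z = drop(GPm %*% S))
}

#' Heritability and effect-structure summary
#'
#' Assembles the full multivariate summary from fitted variance
#' components: trace proportions; eigen-spectra of G P^- and Mat P^-
#' (cumulative fractions reported both over the positive spectrum and over
#' the full trace); the maximum additive heritability `h2_max` (dominant
#' eigenvalue of G P^-) and its maternal analogue `mat_max`; and the
#' pairwise angles between the leading eigenvectors of P, G and Mat.
#'
#' @param vc A `variance_components` object.
#' @param rtol Pseudoinverse cutoff passed to [gp_minus()].
#' @return Object of class `heritability_summary`.
#' @export
heritability_summary <- function(vc, rtol = 1e-10) {
  props <- variance_proportions(vc)
  GPm <- gp_minus(vc$G, vc$P, rtol = rtol)
  MatPm <- gp_minus(vc$Mat, vc$P, rtol = rtol)
  eg <- eigen_summary(GPm)
  em <- eigen_summary(MatPm)
  lead <- function(m) fix_sign_(eigen((m + t(m)) / 2,
                                      symmetric = TRUE)$vectors[, 1L])
  vP <- lead(vc$P); vG <- lead(vc$G); vM <- lead(vc$Mat)
  comp_eig <- lapply(vc[c("P", "G", "Mat", "Pat", "R")], function(m)
    eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(
    proportions = props,
    GPm = GPm, MatPm = MatPm,
    GPm_eigenvalues = eg$values, GPm_eigenvectors = eg$vectors,
    GPm_cumulative = eg$cumulative,
    MatPm_eigenvalues = em$values, MatPm_eigenvectors = em$vectors,
    MatPm_cumulative = em$cumulative,
    h2_max = eg$values[1L], mat_max = em$values[1L],
    component_eigenvalues = comp_eig,
    angles_deg = c(P_G = vector_angle(vP, vG),
                   P_Mat = vector_angle(vP, vM),
                   G_Mat = vector_angle(vG, vM)),
    leading_vectors = list(P = vP, G = vG, Mat = vM)),
    class = "heritability_summary")
}

#' @export
print.heritability_summary <- function(x, ...) {
  cat("Multivariate heritability summary\n")
  cat("  Trace proportions of P: ",
      paste(sprintf("%s = %.4f", names(x$proportions), x$proportions),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  h2_max (dominant eigenvalue of GP-):   %.4f\n", x$h2_max))
  cat(sprintf("  mat_max (dominant eigenvalue of MatP-): %.4f\n", x$mat_max))
  cat("  Angles between leading eigenvectors (deg): ",
      paste(sprintf("%s = %.2f", names(x$angles_deg), x$angles_deg),
            collapse = ", "), "\n", sep = "")
  g1 <- x$component_eigenvalues$G
  m1 <- x$component_eigenvalues$Mat
  cat(sprintf("  Leading eigenvalue share: G %.2f%%, Mat %.2f%%\n",
              100 * g1[1L] / sum(pmax(g1, 0)),
              100 * m1[1L] / sum(pmax(m1, 0))))
  invisible(x)
}
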