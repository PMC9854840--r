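#' Permutation (M)ANOVA on shape variables or a scalar trait
#'
#' One-way (multivariate) analysis of variance with significance assessed
#' by residual randomization: sums of squares are summed squared distances
#' from group means (multivariate response) or squared deviations (scalar),
#' F is the usual mean-square ratio, and the null distribution is obtained
#' by permuting the residuals of the reduced (intercept-only) model. The
#' p-value uses the add-one convention, p = (1 + #{F* >= F}) / (1 + n_perm),
#' so it can never be below 1/(n_perm + 1). The effect size Z standardizes
#' the observed F against the permutation distribution.
#'
#' Typical use: testing sexual dimorphism of head shape (PC scores) and of
#' log centroid size before pooling sexes for the heritability analysis.
#'
#' @param response Numeric vector, matrix of shape variables (rows =
#'   specimens), or a [shape_pca()] result (its scores are used).
#' @param groups Factor (or coercible) of group labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Object of class `perm_test`: `statistic` (F), `effect_size` (Z),
#'   `p_value`, `n_permutations`, `df`, `ss`.
#' @export
procrustes_anova <- function(response, groups, n_perm = 1000L, seed = 1L) {
  if (inherits(response, "shape_pca")) response <- response$scores
  Y <- as.matrix(response)
  groups <- factor(groups)
  n <- nrow(Y)
  if (length(groups) != n)
    stop("groups length does not match the response", call. = FALSE)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("every group needs at least 2 members", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_tot <- sum(Yc^2)
  if (ss_tot <= 1e-12 * n * max(1, max(abs(Y)))^2)
    stop("constant response: no variance to partition", call. = FALSE)
  df_model <- nlevels(groups) - 1L
  df_resid <- n - nlevels(groups)

  f_stat <- function(Yc) {
    gm <- rowsum(Yc, groups) / as.vector(table(groups))
    ss_model <- sum(gm^2 * as.vector(table(groups)))
    ss_resid <- sum(Yc^2) - ss_model
    (ss_model / df_model) / (ss_resid / df_resid)
  }

  f_obs <- f_stat(Yc)
  # residuals of the intercept-only reduced model are the centred data, so
  # residual randomization amounts to permuting rows of Yc
  f_perm <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b)
      f_stat(Yc[sample.int(n), , drop = FALSE]), 0)
  })
  all_f <- c(f_obs, f_perm)
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  z <- if (stats::sd(all_f) > 0) (f_obs - mean(all_f)) / stats::sd(all_f)
       else 0
  ss_model <- f_obs * df_model / df_resid /
    (1 + f_obs * df_model / df_resid) * ss_tot
  structure(list(statistic = f_obs, effect_size = z, p_value = p,
                 n_permutations = as.integer(n_perm),
                 df = c(model = df_model, resid = df_resid),
                 ss = c(model = ss_model, resid = ss_tot - ss_model,
                        total = ss_tot)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation (M)ANOVA: F(%d, %d) = %.4g, Z = %.3g, p = %.4g (%d permutations)\n",
              x$df[1L], x$df[2L], x$statistic, x$effect_size, x$p_value,
              x$n_permutations))
  invisible(x)
}
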