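# A small shared fixture: crossed dam x sire families with known
# components (default: 7 founders, 24 offspring in 6 families).
small_fixture <- function(seed = 3L, t = 2L, G = NULL, Mat = NULL,
                          Pat = NULL, R = NULL, n_dams = 4L, n_sires = 3L,
                          n_fam = 6L, fam_size = 4L) {
  ped <- simulate_pedigree(n_dams, n_sires, n_fam, rep(fam_size, n_fam),
                           seed = seed)
  n <- nrow(ped)
  if (is.null(G)) G <- matrix(c(2, 0.5, 0.5, 1), 2L)[seq_len(t), seq_len(t)]
  if (is.null(Mat)) Mat <- diag(c(1, 0.5))[seq_len(t), seq_len(t), drop = FALSE]
  if (is.null(Pat)) Pat <- diag(0.3, t)
  if (is.null(R)) R <- diag(t)
  a <- simulate_breeding_values(ped, G, seed = seed + 1L)
  set.seed(seed + 2L)
  dams <- unique(stats::na.omit(ped$dam))
  sires <- unique(stats::na.omit(ped$sire))
  me <- morphherit:::rmvn_(length(dams), Mat); rownames(me) <- dams
  pe <- morphherit:::rmvn_(length(sires), Pat); rownames(pe) <- sires
  m <- matrix(0, n, t); k <- !is.na(ped$dam); m[k, ] <- me[ped$dam[k], ]
  p <- matrix(0, n, t); k <- !is.na(ped$sire); p[k, ] <- pe[ped$sire[k], ]
  e <- morphherit:::rmvn_(n, R)
  lcs <- rnorm(n, 3, 0.2)
  Y <- a + m + p + e + outer(lcs - mean(lcs), seq_len(t) / 2)
  list(ped = ped, Y = Y, lcs = lcs,
       data = animal_model_data(Y, lcs, ped$id, ped))
}

test_that("restricted likelihood matches the dense GLS oracle at the
           returned estimates", {
  fx <- small_fixture(seed = 3L, t = 2L)
  vc <- reml_fit(fx$data, fx$ped, max_iter = 40L)
  A <- relationship_matrix(fx$ped)[fx$data$ids, fx$data$ids]
  oracle <- oracle_restricted_logl(fx$Y, fx$lcs, A, fx$data$dam,
                                   fx$data$sire, vc$G, vc$Mat, vc$Pat,
                                   vc$R)
  expect_equal(vc$logL, oracle, tolerance = 1e-6)

  # and at arbitrary (non-optimal) component values, via the optimizer's
  # first recorded likelihood under a forced start
  S <- stats::cov(fx$Y)
  start <- list(G = S / 3, Mat = S / 5, Pat = S / 6, R = S / 2)
  vc0 <- reml_fit(fx$data, fx$ped, start = start, max_iter = 1L,
                  accelerate = FALSE)
  oracle0 <- oracle_restricted_logl(fx$Y, fx$lcs, A, fx$data$dam,
                                    fx$data$sire, S / 3, S / 5, S / 6,
                                    S / 2)
  expect_equal(vc0$logL_path[1L], oracle0, tolerance = 1e-6)
})

test_that("pure EM iterations never decrease the restricted likelihood", {
  fx <- small_fixture(seed = 11L, t = 2L)
  vc <- reml_fit(fx$data, fx$ped, max_iter = 60L, accelerate = FALSE)
  expect_true(all(diff(vc$logL_path) >= -1e-9))
})

test_that("fitted components are symmetric PSD and P is their sum", {
  fx <- small_fixture(seed = 5L, t = 2L)
  vc <- reml_fit(fx$data, fx$ped, max_iter = 40L)
  for (nm in c("G", "Mat", "Pat", "R")) {
    M <- vc[[nm]]
    expect_lt(max(abs(M - t(M))), 1e-10)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(1, max(abs(ev))))
  }
  expect_equal(vc$P, vc$G + vc$Mat + vc$Pat + vc$R)
})

test_that("estimates are invariant to the order of observation rows", {
  # larger families than the base fixture: a sharper optimum lets both
  # orderings be driven to the same point
  fx <- small_fixture(seed = 7L, t = 2L, n_dams = 8L, n_sires = 6L,
                      n_fam = 12L, fam_size = 6L)
  set.seed(70)
  perm <- sample(seq_len(nrow(fx$Y)))
  d2 <- animal_model_data(fx$Y[perm, ], fx$lcs[perm], fx$ped$id[perm],
                          fx$ped)
  ctrl <- list(max_iter = 1500L, tol_logl = 1e-12, tol_par = 1e-10)
  v1 <- do.call(reml_fit, c(list(fx$data, fx$ped), ctrl))
  v2 <- do.call(reml_fit, c(list(d2, fx$ped), ctrl))
  expect_lt(max(abs(v1$G - v2$G)), 1e-8)
  expect_lt(max(abs(v1$Mat - v2$Mat)), 1e-8)
  expect_lt(max(abs(v1$R - v2$R)), 1e-8)
})

test_that("constant traits yield zero variance everywhere", {
  ped <- simulate_pedigree(2L, 2L, 3L, rep(4L, 3L), seed = 2L)
  Y <- matrix(5, nrow(ped), 2L)
  d <- animal_model_data(Y, rnorm(nrow(ped), 3, 0.1), ped$id, ped)
  vc <- reml_fit(d, ped)
  expect_lt(sum(diag(vc$G)) + sum(diag(vc$Mat)) + sum(diag(vc$Pat)) +
              sum(diag(vc$R)), 1e-8)
})

test_that("balanced half-sib sire variance matches the ANOVA
           expectation-of-mean-squares estimator", {
  n_sires <- 15L; m <- 12L
  set.seed(41)
  sires <- rep(sprintf("S%02d", seq_len(n_sires)), each = m)
  y <- rnorm(n_sires)[factor(sires)] * sqrt(0.4) +
    rnorm(n_sires * m, sd = sqrt(0.8))
  ids <- c(unique(sires), paste0("O", seq_along(y)))
  ped <- pedigree(id = ids, dam = rep(NA, length(ids)),
                  sire = c(rep(NA, n_sires), sires))
  # constant covariate collapses the fixed part to the intercept, the
  # setting where balanced-design REML equals the EMS estimator
  d <- animal_model_data(cbind(y), rep(0, length(y)),
                         paste0("O", seq_along(y)), ped)
  vc <- reml_fit(d, ped, components = "paternal", max_iter = 2000L,
                 tol_logl = 1e-13, tol_par = 1e-9)
  ref <- oracle_halfsib_anova(y, sires)
  expect_gt(unname(ref["between"]), 0)  # estimator inside parameter space
  expect_equal(unname(vc$Pat[1L, 1L]), unname(ref["between"]),
               tolerance = 1e-6)
  expect_equal(unname(vc$R[1L, 1L]), unname(ref["within"]),
               tolerance = 1e-6)
})

test_that("preconditions are enforced", {
  fx <- small_fixture(seed = 3L, t = 2L)
  expect_error(reml_fit(fx$data, ped = NULL), "ped is NULL")
  ped1 <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  d1 <- animal_model_data(cbind(rnorm(3)), rnorm(3), c("A", "B", "C"),
                          ped1)
  expect_error(reml_fit(d1, ped1), "dams")
  expect_error(animal_model_data(fx$Y, fx$lcs, rep("zz", nrow(fx$Y)),
                                 fx$ped), "one phenotype row")
})

test_that("uninformative parent labels with no genetic signal give
           near-zero component estimates", {
  # reduced design: 20 dams x 15 sires, 300 offspring, t = 2, 10 seeds
  props <- t(vapply(1:10, function(sd) {
    ped <- simulate_pedigree(20L, 15L, 30L, rep(10L, 30L), seed = sd)
    n <- nrow(ped)
    set.seed(sd + 900L)
    Y <- morphherit:::rmvn_(n, diag(2))       # pure residual variation
    shuffle <- sample(which(!ped$founder))
    ped$dam[!ped$founder] <- ped$dam[shuffle]  # break family structure
    ped$sire[!ped$founder] <- ped$sire[shuffle]
    d <- animal_model_data(Y, rnorm(n, 3, 0.1), ped$id, ped)
    vc <- reml_fit(d, ped, max_iter = 25L, tol_logl = 1e-5,
                   tol_par = 1e-3)
    variance_proportions(vc)[c("G", "Mat", "Pat")]
  }, numeric(3L)))
  expect_true(all(apply(props, 2L, stats::median) < 0.1))
})
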