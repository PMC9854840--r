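test_that("simulated pedigrees honour the breeding design", {
  ped <- simulate_pedigree(8L, 6L, 12L, c(rep(19L, 5L), rep(18L, 7L)),
                           seed = 1L)
  expect_equal(nrow(ped), 235L)
  expect_equal(sum(!ped$founder), 221L)
  expect_equal(sum(ped$founder), 14L)
  # every dam and sire used, all 12 pairs distinct
  fams <- unique(paste(ped$dam[!ped$founder], ped$sire[!ped$founder]))
  expect_length(fams, 12L)
  expect_length(unique(stats::na.omit(ped$dam)), 8L)
  expect_length(unique(stats::na.omit(ped$sire)), 6L)

  # two maternal half-sib families sharing the single sire
  ped2 <- simulate_pedigree(2L, 1L, 2L, c(3L, 3L), seed = 7L)
  expect_equal(nrow(ped2), 9L)
  expect_length(unique(stats::na.omit(ped2$sire)), 1L)

  # determinism under the seed
  expect_identical(simulate_pedigree(8L, 6L, 12L, rep(18L, 12L), seed = 5L),
                   simulate_pedigree(8L, 6L, 12L, rep(18L, 12L), seed = 5L))
  expect_error(simulate_pedigree(2L, 2L, 5L, rep(1L, 5L)), "pairs exist")
})

test_that("breeding values follow the pedigree recursion", {
  ped <- simulate_pedigree(3L, 2L, 4L, rep(3L, 4L), seed = 9L)
  # G = 0 gives exactly zero breeding values
  a0 <- simulate_breeding_values(ped, matrix(0, 2L, 2L), seed = 1L)
  expect_true(all(a0 == 0))

  # parent-average regression: cov(midparent, offspring) = G/2
  big <- pedigree(id = c("D", "S", sprintf("O%04d", 1:4000)),
                  dam = c(NA, NA, rep("D", 4000L)),
                  sire = c(NA, NA, rep("S", 4000L)))
  a <- simulate_breeding_values(big, matrix(1), seed = 21L)
  kids <- a[-(1:2), 1L]
  expect_equal(mean(kids), (a[1L] + a[2L]) / 2, tolerance = 0.06)
  expect_equal(var(kids), 0.5, tolerance = 0.05)

  # empirical covariance across replicates matches G (x) A elementwise
  ped10 <- pedigree(
    id   = c("F1", "F2", "F3", "A", "B", "C", "D", "E", "H", "I"),
    dam  = c(NA, NA, NA, "F1", "F1", "F3", "A", "A", "C", "D"),
    sire = c(NA, NA, NA, "F2", "F2", "B", "B", "C", "B", "H"))
  A <- relationship_matrix(ped10)
  reps <- 2000L
  vals <- vapply(seq_len(reps), function(r)
    simulate_breeding_values(ped10, matrix(1), seed = 10000L + r)[, 1L],
    numeric(10L))
  Ahat <- tcrossprod(vals - rowMeans(vals)) / (reps - 1L)
  se <- sqrt((A^2 + outer(diag(A), diag(A))) / reps)
  expect_true(all(abs(Ahat - A) <= 3 * se))
})

test_that("a noiseless degenerate truth reproduces the template exactly", {
  ped <- simulate_pedigree(2L, 2L, 3L, rep(4L, 3L), seed = 3L)
  z3 <- matrix(0, 3L, 3L)
  tr <- simulation_truth(z3, z3, z3, z3, cs_sd = 0, asym_noise_sd = 0,
                         seed = 3L)
  sim <- simulate_dataset(tr, ped)
  al <- gpa(sim$configs)
  expect_lt(sum(apply(al$shapes, 2L, stats::var)), 1e-16)
  expect_equal(al$centroid_sizes, rep(exp(tr$cs_mean), nrow(ped)),
               tolerance = 1e-9)
})

test_that("without digitization noise all variation is symmetric", {
  sch <- viper_head_scheme()
  ped <- simulate_pedigree(3L, 2L, 4L, rep(6L, 4L), seed = 6L)
  base <- simulation_preset("recovery", seed = 6L)$truth
  tr <- simulation_truth(base$G, base$Mat, base$Pat, base$R,
                         beta = base$beta, asym_noise_sd = 0, seed = 6L)
  sim <- simulate_dataset(tr, ped)
  al <- gpa(sim$configs, sch, proj = FALSE)
  sy <- symmetric_component(al, sch, proj = FALSE)
  for (i in c(1L, 5L, 20L)) {
    a <- morphherit:::unflatten_(al$shapes[i, ])
    s <- morphherit:::unflatten_(sy$shapes[i, ])
    R <- morphherit:::rot_fit_(a, s)
    expect_lt(max(abs(a %*% R - s)), 1e-8)
  }
})

test_that("symmetrization removes more variance as asymmetric noise
           grows", {
  sch <- viper_head_scheme()
  ped <- simulate_pedigree(3L, 2L, 4L, rep(8L, 4L), seed = 10L)
  base <- simulation_preset("recovery", seed = 10L)$truth
  removed <- vapply(c(0.001, 0.003, 0.009), function(sdv) {
    tr <- simulation_truth(base$G, base$Mat, base$Pat, base$R,
                           asym_noise_sd = sdv, seed = 10L)
    sim <- simulate_dataset(tr, ped)
    al <- gpa(sim$configs, sch, proj = TRUE)
    sy <- symmetric_component(al, sch)
    tot <- sum(apply(al$shapes, 2L, stats::var))
    tot_sym <- sum(apply(sy$shapes, 2L, stats::var))
    tot - tot_sym
  }, 0)
  expect_true(all(removed > 0))
  expect_true(all(diff(removed) > 0))
})

test_that("simulated datasets are exactly reproducible under a seed", {
  ped <- simulate_pedigree(3L, 2L, 4L, rep(5L, 4L), seed = 2L)
  tr <- simulation_preset("recovery", seed = 2L)$truth
  s1 <- simulate_dataset(tr, ped)
  s2 <- simulate_dataset(tr, ped)
  expect_identical(s1$truth_table, s2$truth_table)
  expect_identical(s1$configs[[17L]]$coords, s2$configs[[17L]]$coords)
})

test_that("trait dimension cannot exceed the symmetric-space dimension", {
  big <- diag(39L)
  expect_error(simulation_truth(big, big, big, big), "38")
})

test_that("realized covariance of trait deviations converges to
           G + Mat + Pat + R under independent parents", {
  # one offspring per family: every a, m, p, e draw independent across rows
  n_fam <- 600L
  ped <- simulate_pedigree(n_fam, n_fam, n_fam, rep(1L, n_fam), seed = 14L)
  base <- simulation_preset("recovery", seed = 14L)$truth
  tr <- simulation_truth(base$G, base$Mat, base$Pat, base$R,
                         beta = rep(0, 3L), seed = 14L)
  sim <- simulate_dataset(tr, ped, phenotyped = ped$id[!ped$founder])
  z <- as.matrix(sim$truth_table[, c("z.1", "z.2", "z.3")])
  Ptrue <- tr$G + tr$Mat + tr$Pat + tr$R
  err <- max(abs(stats::cov(z) - Ptrue)) / max(diag(Ptrue))
  expect_lt(err, 0.15)
})
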