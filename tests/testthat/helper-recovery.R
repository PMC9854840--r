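# Shared parameter-recovery harness: the 20-seed simulation/refit study at
# the standard recovery design (t = 3, 40 dams, 30 sires, 800 offspring).
# Computed once per test run and cached, because several properties are
# checked against the same fits.

.recovery_cache <- new.env(parent = emptyenv())

recovery_results <- function(n_seeds = 20L) {
  key <- paste0("seeds", n_seeds)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  sch <- viper_head_scheme()
  runs <- lapply(seq_len(n_seeds), function(sd) {
    ps <- simulation_preset("recovery", seed = sd)
    sim <- simulate_dataset(ps$truth, ps$ped)
    al <- gpa(sim$configs, sch, slide = TRUE)
    sy <- symmetric_component(al, sch)
    pc <- shape_pca(sy, n_retained = 3L)
    amd <- animal_model_data(pc$scores, log(sy$centroid_sizes), sy$ids,
                             ps$ped)
    vc <- reml_fit(amd, ps$ped, max_iter = 20L, tol_logl = 1e-5,
                   tol_par = 1e-3)
    true_P <- ps$truth$G + ps$truth$Mat + ps$truth$Pat + ps$truth$R
    list(est = variance_proportions(vc),
         true = variance_proportions(ps$truth),
         h2_est = heritability_summary(vc)$h2_max,
         h2_true = max(eigen(ps$truth$G %*% solve(true_P))$values),
         gpm_eigen = heritability_summary(vc)$GPm_eigenvalues,
         vc = vc)
  })
  .recovery_cache[[key]] <- runs
  runs
}
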