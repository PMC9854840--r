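# morphherit

Quantitative-genetic analysis of 2-D landmark shape from pedigreed
breeding data: how much of the variation in a shape — the motivating case
is the dorsal head shape of captive-bred Hungarian meadow vipers, 40
landmarks per specimen — is additive-genetic, how much is due to the
identity of the mother or the father, and how much is residual?

The package covers the whole path from raw files to heritability
summaries:

* **Morphometrics** — TPS landmark files in; Generalized Procrustes
  Analysis with bending-energy sliding of semilandmarks; object-symmetry
  averaging (removes asymmetry exactly); PCA of the symmetric shape
  variables; permutation (M)ANOVA for sexual dimorphism.
* **Quantitative genetics** — pedigree tables in; numerator relationship
  matrix **A** by the tabular method; multivariate REML for the animal
  model
  `y = Xβ + a + m_dam + p_sire + e`, with
  `a ~ N(0, G ⊗ A)`, `m ~ N(0, Mat ⊗ I)`, `p ~ N(0, Pat ⊗ I)`,
  `e ~ N(0, R ⊗ I)` and log centroid size as a fixed covariate. Updates
  are exact EM (monotone, PSD by construction) with average-information
  acceleration and Aitken extrapolation.
* **Heritability** — `P = G + Mat + Pat + R`; trace proportions; the
  multivariate heritability matrix `GP⁻` (P⁻ the Moore–Penrose
  pseudoinverse) and its maternal analogue `MatP⁻`; the maximum
  heritability `h²_max` (dominant eigenvalue of `GP⁻`); eigenvector
  angles; predicted selection responses `Δz̄ = GP⁻S`; back-projection of
  any trait-space vector to a landmark displacement field.
* **Simulation** — a generator that emulates the crossed breeding design
  (e.g., 12 families from 8 dams × 6 sires with 221 offspring) and
  produces landmark datasets with *known* covariance components, so every
  stage is verifiable by parameter recovery.

## Worked example

Simulate a dataset at the emulated study design (235 specimens: 8 dams,
6 sires, 221 offspring), then run the full analysis:

```r
library(morphherit)

ps  <- simulation_preset("viper", seed = 42)
sim <- simulate_dataset(ps$truth, ps$ped)
write_tps(sim$configs, "shapes.tps")
write_pedigree(ps$ped, "pedigree.csv")

scheme  <- viper_head_scheme()
configs <- read_tps("shapes.tps", scheme)
ped     <- read_pedigree("pedigree.csv")
aligned <- gpa(configs, scheme, slide = TRUE)
symm    <- symmetric_component(aligned, scheme)
space   <- shape_pca(symm, n_retained = 3)
space
#> Shape PCA: 235 specimens, 38 positive eigenvalues, 3 retained
#>  PC eigenvalue proportion cumulative
#>   1 2.3474e-04     0.4801     0.4801
#>   2 9.6477e-05     0.1973     0.6774
#>   3 2.2531e-05     0.0461     0.7234
```

The 38 positive eigenvalues are the dimension of the symmetric shape
space of this landmark scheme (18 bilateral pairs and 4 midline points:
2·18 + 4 − 2). Check sexual dimorphism (none here, by construction),
then fit the animal model and summarize:

```r
procrustes_anova(space$scores, ped$sex[match(space$ids, ped$id)],
                 n_perm = 1000, seed = 1)
#> Permutation (M)ANOVA: F(1, 233) = 0.03198, Z = -0.924, p = 0.984 (1000 permutations)

amd  <- animal_model_data(space$scores, log(symm$centroid_sizes),
                          space$ids, ped)
vc   <- reml_fit(amd, ped, max_iter = 200)
summ <- heritability_summary(vc)
summ
#> Multivariate heritability summary
#>   Trace proportions of P: G = 0.5358, Mat = 0.3699, Pat = 0.0605, R = 0.0338
#>   h2_max (dominant eigenvalue of GP-):   0.8624
#>   mat_max (dominant eigenvalue of MatP-): 0.8261
#>   Angles between leading eigenvectors (deg): P_G = 13.65, P_Mat = 55.84, G_Mat = 69.48
#>   Leading eigenvalue share: G 92.25%, Mat 82.70%
```

The generator's true trace proportions were G 0.4913, Mat 0.5069,
Pat ≈ 0, R 0.0018: with only eight dams and six sires the point estimates
scatter around the truth exactly as a design this small predicts, while
the structural quantities — the near-zero paternal share, the dominant-
eigenvector concentration of G and Mat, and the large G–Mat angle (69.5°
estimated vs. 72.5° injected) — are recovered. Predicted response to
selection on PC1 and the corresponding landmark displacement field:

```r
predict_response(summ$GPm, S = c(0.01, 0, 0))$delta_z
#>      PC1      PC2      PC3
#>  0.00863 -0.00004  0.00010
arrows <- back_project(summ$GPm_eigenvectors[, 1], space)  # 2k displacement
```

`run_pipeline("cfg.yaml")` executes the same sequence from a YAML
configuration and writes every intermediate table, a JSON heritability
report, the REML fit log, and a manifest.

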