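---
title: "Methods: partitioning landmark-shape variance with an animal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning landmark-shape variance with an animal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

morphherit estimates how much of the variation in a two-dimensional
landmark-based shape — the dorsal head shape of captive-bred meadow vipers
is the motivating system — is attributable to additive genetic variance
(G), to the identity of the mother (Mat), to the identity of the father
(Pat), and to residual environmental variance (R). The data are photographs
digitized as 40 landmarks per specimen, together with a pedigree from a
controlled breeding design in which a small number of dams and sires are
crossed into full-sib families, so maternal and paternal half-sib links
exist alongside parent–offspring links.

The pipeline has two halves. Geometric morphometrics turns raw landmark
coordinates into shape variables: Generalized Procrustes Analysis (GPA)
removes position, scale and orientation; semilandmarks on outlines slide
to remove arbitrary point spacing along curves; object-symmetry averaging
removes asymmetric variation; principal components of the symmetrized
coordinates are the traits. Quantitative genetics then fits a multivariate
animal model to those traits by REML and summarizes heritability through
the eigenstructure of \(G P^{-}\).

# The morphometric model

## Superimposition

Each configuration of \(k = 40\) landmarks is centred and scaled to unit
centroid size (CS, the square root of the summed squared distances of
landmarks from their centroid); a rotation is then fitted to the current
consensus by the cross-covariance SVD, and the consensus is recomputed,
iterating until its root-mean-square change is below \(10^{-10}\) (at most
100 iterations). This is a partial Procrustes fit: specimens keep exactly
unit centroid size. Orthogonal tangent-space projection is available
(`proj`); `gpa()` leaves it off by default so aligned configurations retain
exactly unit size, while `symmetric_component()` applies it by default
because the downstream PCA and variance decomposition assume a linear
trait space. Without projection, aligned shapes lie on a unit sphere and
the sphere's radial curvature direction contributes a small spurious
principal component; with projection, the symmetric shape space of a
scheme with \(p\) bilateral pairs and \(m\) midline landmarks has linear
dimension exactly \(2p + m - 2\) (the \(-2\) removes translation along the
midline and scale) — 38 for the 18-pair, 4-midline head scheme, which is
why a PCA of at least 39 symmetrized specimens has exactly 38 positive
eigenvalues.

## Sliding semilandmarks

Twelve of the 40 points trace the supraocular outline and the posterior
head border and have no exact anatomical correspondence. During
superimposition each such point may slide along the chord between its two
scheme-declared neighbours; slide amounts are chosen to minimize the
thin-plate-spline bending energy of the specimen's deviation from the
consensus (the bending-energy matrix is rebuilt from the current consensus
each cycle). Sliding and re-superimposition alternate for at most five
cycles or until the coordinate change drops below \(10^{-8}\).

A known limitation: with the reference updating every cycle, prolonged
iteration lets the semilandmarks of all specimens drift coherently along
the outline — the bending-energy criterion penalizes such common-mode
tangential motion only weakly. The five-cycle cap is therefore part of
the procedure itself: each sliding pass strictly reduces bending energy
against the current consensus (the test suite checks this), and the cap
bounds how far the weakly-determined common mode can wander.

## Object symmetry

For a bilaterally symmetric structure, each configuration is paired with
its mirror image (first coordinate negated) with left/right labels swapped
according to the scheme; originals and reflected copies are superimposed
together. The consensus of that joint fit is constrained at every
iteration to exact bilateral symmetry with the midline landmarks on the
second coordinate axis (midline orientation fitted by least squares).
Because the consensus is exactly symmetric, the optimal rotations of a
configuration and of its reflected copy commute with the reflection, and
the average of the two aligned copies — the symmetric component — is
exactly mirror-symmetric; a final explicit symmetrization removes the
remaining floating-point asymmetry, so paired landmarks mirror each other
to machine precision. Asymmetry itself (directional or fluctuating) is
discarded, not analyzed.

## Shape variables and the dimorphism check

PCA of the covariance matrix of the symmetrized coordinates yields
orthonormal loadings; the leading scores (default 15, configurable) are
the traits passed to the genetic model. Sexual dimorphism is checked
beforehand with a one-way permutation (M)ANOVA on the shape scores and on
log CS (adults and offspring separately): F is the ratio of mean squares
computed from summed squared distances, and significance comes from
residual randomization of the intercept-only reduced model — equivalent
here to permuting rows — with \(p = (1 + \#\{F^* \ge F\})/(1 + N)\), 1000
permutations by default. Sexes are pooled for the heritability analysis
regardless of the outcome; the test is reported, not used as a gate.

# The quantitative-genetic model

For \(t\) traits per individual the animal model is
\[
y = X\beta + a + m_{\mathrm{dam}} + p_{\mathrm{sire}} + e,
\]
with \(a \sim N(0, G \otimes A)\) (A the numerator relationship matrix
from the pedigree, built by the tabular method), \(m \sim N(0, Mat \otimes
I)\) over dam identities, \(p \sim N(0, Pat \otimes I)\) over sire
identities, and \(e \sim N(0, R \otimes I)\). Fixed effects are an
intercept and centred log CS per trait, absorbing allometry. Maternal and
paternal effects are identity-indexed (environmental-style, i.i.d. across
parents); no genetic maternal effect or direct–maternal covariance is
modelled. The total phenotypic covariance is \(P = G + Mat + Pat + R\),
and the relative importance of each source is its trace divided by
\(\operatorname{trace}(P)\).

## REML

Because non-phenotyped pedigree members contribute nothing to the
restricted likelihood, estimation marginalizes to the phenotyped
individuals: \(V = G \otimes A_{oo} + Mat \otimes DD' + Pat \otimes SS' +
R \otimes I\), with \(A_{oo}\) the relationship submatrix of observed ids
and \(DD'\), \(SS'\) shared-dam/shared-sire indicators. The restricted
log-likelihood is \(-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]\) (the
additive constant is omitted; comparisons are meaningful within a
dataset).

The optimizer combines three update types:

* **Exact EM** — the conditional-expectation update
  \(\Theta \leftarrow \Theta + \Theta(W - T)\Theta / q\), where \(W\) and
  \(T\) collect the quadratic forms and traces of the projection matrix.
  It is monotone in the restricted likelihood and keeps every component
  symmetric positive semidefinite by construction.
* **Average-information (AI) acceleration** — a Newton-type step taken on
  the lower Cholesky factors of the free components (so proposals cannot
  leave the PSD cone), accepted only if the likelihood does not decrease,
  with step halving and fall-back to EM. After repeated rejections AI
  rests for a few iterations to avoid wasted line searches.
* **Aitken extrapolation** — when two successive EM directions are nearly
  proportional (the linear tail that EM exhibits along the
  G-versus-maternal likelihood ridge typical of these designs), the
  geometric-series limit is tried and kept only if it improves the
  likelihood.

Components whose trace collapses below \(10^{-7}\) of the phenotypic
scale are pinned at exactly zero for the remaining iterations; a
true-zero paternal component otherwise makes every joint Newton step fail
near the boundary. Starting values are method-of-moments estimates from
parent–offspring, maternal half-sib, and paternal half-sib residual
cross-covariances (falling back to the sample covariance divided by four
where the design lacks a pair class). Convergence requires both
\(|\Delta \log L| <\) `tol_logl` (default \(10^{-8}\)) and a maximum
relative parameter change below `tol_par` (default \(10^{-6}\));
non-convergence at `max_iter` flags the result rather than erroring.
Degenerate zero-variance input returns all-zero components directly.

## Heritability summaries

Multivariate heritability is \(G P^{-}\), with \(P^{-}\) the Moore–Penrose
pseudoinverse (SVD with relative cutoff \(10^{-10}\), configurable). The
matrix is used exactly in that asymmetric form; its eigenvalues are real
whenever the components are valid (it is similar to a symmetric PSD
matrix), and an imaginary magnitude above \(10^{-8}\) is treated as an
error signalling invalid inputs. The dominant eigenvalue is the maximum
additive heritability \(h^2_{max}\); \(Mat\,P^{-}\) gives the maternal
analogue. Angles between leading eigenvectors of P, G and Mat use the
absolute dot product, so they land in \([0^\circ, 90^\circ]\) regardless
of eigenvector sign conventions (eigenvector signs themselves are fixed so
the largest-magnitude element is positive). Predicted selection responses
follow the generalized breeders' equation \(\Delta\bar z = G P^{-} S\),
and any trait-space vector can be mapped back to a landmark-displacement
field through the orthonormal PCA loadings for plotting. Cumulative
eigenvalue fractions are reported both over the positive spectrum and
over the full trace, since the two conventions differ for indefinite
estimates.

# The synthetic-data generator

`simulate_pedigree()` builds the crossed design: families are distinct
dam × sire pairs, every dam and sire is used at least once, and family
sizes are supplied. `simulate_breeding_values()` runs the Mendelian
recursion (founders \(N(0, G)\); non-founders parent-average plus a
sampling deviation with covariance \((\tfrac12 - \tfrac14(F_d + F_s))G\)).
`simulate_dataset()` composes trait-space deviations \(\beta(\log CS -
\mu) + a + m + p + e\), maps them to landmarks through a fixed orthonormal
basis of the symmetric tangent space at a synthetic, exactly symmetric
head-shaped template, adds i.i.d. asymmetric digitization noise per
coordinate, and hides everything behind random rotation, translation and
scale \(e^{\log CS}\). Injecting variance only into the symmetric
subspace means true covariance components live in (a rotation of) the
same space the pipeline estimates in, so trace proportions and
\(h^2_{max}\) are directly comparable between truth and estimate.

Two presets encode the emulated breeding designs:

* `"viper"` — 12 families from 8 dams × 6 sires, 221 offspring (five
  families of 19 and seven of 18; the offspring total is part of the
  design, the per-family breakdown is a free choice, so near-equal sizes
  are used), trace
  proportions G 49.13%, Mat 50.69%, Pat \(8.85\times10^{-4}\)%, the rest
  residual, with G and Mat eigenstructure concentrated on leading axes
  about \(72.5^\circ\) apart.
* `"recovery"` — 40 dams × 30 sires and 800 offspring with proportions
  0.45 : 0.45 : 0 : 0.10. The number of families is not dictated by those
  totals; 80 families of 10 are used so each dam and sire appears in
  about two or three families, giving the maternal/paternal half-sib
  contrast that makes G separable from Mat.

Generator defaults chosen where no study value exists, at magnitudes a
morphometrician would call realistic: total symmetric shape variance
\(4.5\times10^{-4}\) squared Procrustes units; log CS mean \(\log 25\)
with SD 0.15 (head sizes in image units); allometric slope contributing a
few percent of trait-1 variance; digitization noise SD 0.002 shape units
per coordinate (about 0.2% of centroid size, typical for careful
digitizing) — small, asymmetric, and removed almost entirely by the
symmetric component.

What the generator does **not** emulate: curved-outline resampling before
sliding (deviations displace semilandmarks off simple chords), clutch or
cohort environmental effects beyond dam identity, ontogenetic allometry
beyond a single log CS slope, multiple paternity, or non-Gaussian
digitization error. Passing parameter-recovery tests therefore shows the
estimation machinery is correct under the stated model, not that the
model captures every feature of real photographs.

# Verification strategy and problem sizes

Every numerical core is checked against an independent oracle written
from the definition: GPA against a dense grid search over rotation
angles; the relationship matrix against gene dropping (200,000 allele
drops, three standard errors); the restricted likelihood against a dense
GLS formula assembled with `kronecker()` and `solve()`; the pseudoinverse
product against an independent implementation; eigenvalues against
characteristic-polynomial roots; balanced half-sib REML against the
expectation-of-mean-squares ANOVA estimator, which it must equal
exactly when the latter is inside the parameter space.

End-to-end parameter recovery runs the full pipeline (simulate → GPA with
sliding → symmetric component → PCA → REML → summaries) over 20 seeds at
the recovery preset, requiring median absolute errors of the trace
proportions below 0.10, a true-zero paternal proportion recovered below
0.02 in median, and \(h^2_{max}\) within 0.1. Those fits use
`max_iter = 20` with `tol_logl = 1e-5`, a problem-size choice: the
criteria concern trace proportions, which settle long before the late
iterations that only creep along the flat G/Mat likelihood ridge. The null-calibration property (shuffled parent labels, no
genetic signal) runs at a reduced design — 20 dams × 15 sires, 300
offspring, two traits, ten seeds — which is ample to detect spurious
variance absorption. The permutation-test calibration uses 200 null
datasets of 40 specimens at 500 permutations.

# Numerical choices collected

* GPA convergence \(10^{-10}\) on the consensus RMS change, 100-iteration
  cap, error on non-convergence.
* Bending-energy sliding restricted to chord directions; reference is the
  current consensus; at most 5 slide/align cycles or change
  \(< 10^{-8}\).
* Mirror axis: first coordinate axis after the consensus midline is
  aligned to the second axis by least squares; orientation ties broken
  toward the previous consensus.
* PCA eigenvalues below \(10^{-10}\) of the largest count as zero;
  retention default 15, never silently capped.
* Pseudoinverse cutoff \(10^{-10}\) relative, configurable per call.
* Eigenvector sign: largest-magnitude element positive. Angles via
  absolute dot product.
* REML: tolerances \(10^{-8}\) (likelihood) and \(10^{-6}\) (relative
  parameters); residual floor \(10^{-12}\) of the phenotypic scale;
  boundary pinning at \(10^{-7}\) of that scale; `max_iter` 2000.
* All simulation randomness flows through a single user seed; the RNG
  state of the caller is restored afterwards.

# Known limitations

* Semilandmark drift under prolonged sliding, discussed above.
* With eight dams, maternal variance rests on eight realized maternal
  effects; sampling error of Mat at an 8-dam design is large, and
  the flat G/Mat likelihood ridge means REML point estimates inherit that
  uncertainty. The package reports point estimates only (no standard
  errors), matching its reporting scope.
* The GP⁻ form is used exactly as defined (not the symmetrized
  \(P^{-1/2} G P^{-1/2}\)); for estimates near the PSD boundary its
  eigenvalues can acquire tiny imaginary parts, which are guarded, not
  silently dropped.
* Unknown-parent groups, founder inbreeding, genomic relationship
  matrices, Bayesian animal models and genetic maternal effects are out
  of scope.
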