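---
title: "Methods: dietary niche inference from two tracers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary niche inference from two tracers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `trophoniche`, the
choices that were genuinely open when it was designed, and what the test
suite does and does not demonstrate about real data.

## The mixing model

A consumer's tissue carries two tracers, δ13C and δ15N (per mil). If it
feeds on K prey sources in proportions `p` (a point on the K-simplex), its
expected tracer values are the diet-weighted source means shifted by the
trophic discrimination factor (TDF), and — under the *process error*
formulation — all scatter around that expectation comes from uncertainty in
the source signatures and the TDF:

    mean_i = Σ_k p_k (μ_ik + λ_i)
    var_i  = Σ_k p_k² (σ_ik² + τ_ik²)

`μ_ik, σ_ik` are plug-in sample moments of source k for tracer i; `λ_i, τ_i`
are the TDF mean and SD. There is no separate residual term: a consumer
eating a homogeneous diet is expected to scatter exactly as much as the
sources and TDF do, weighted by the squared proportions. A consequence worth
knowing: `Σ p²` is smallest for even diets, so when a group of consumers is
unusually tight relative to its sources, the likelihood prefers more even
diets. This matters for the clustering interaction discussed below.

Default TDFs are 1.0 ± 0.5 ‰ (carbon) and 1.7 ± 0.5 ‰ (nitrogen), the
mid-range of values estimated for cetacean skin, with deliberately wide SDs
reflecting the absence of controlled feeding studies for large whales. Both
are configurable (`tdf_spec()`).

Elemental concentration weighting is omitted entirely: diets are
proportions of assimilated tracer mass with no [C]/[N] rescaling of
sources.

### Parameterization and priors

Diets are sampled on isometric log-ratio (ILR) coordinates — a fixed
Helmert-type orthonormal basis maps the simplex interior to R^(K−1). Each
consumer group g has a coordinate vector θ_g (fixed effect); each individual
j adds a deviation η_j ~ Normal(0, ω²I) (random effect, nested in its
group), so individual diets are `p_j = ilr⁻¹(θ_g + η_j)`. The basis choice
is unobservable: results are reported on the simplex.

The prior on group diets is Dirichlet (flat, concentration 1, by default),
induced *exactly* on θ through the ILR Jacobian: up to a constant,
`log prior(θ_g) = Σ_k α_k log p_k(θ_g)`. A prior-only run
(`fit_mixing_model(..., likelihood = FALSE)`) is tested to recover the
Dirichlet's analytic mean and variance, which pins the Jacobian down
numerically. The random-effect scale ω gets a half-normal prior with scale 2
(ILR units) — broad enough to be dominated by data when individuals truly
differ, and a pure design choice, since nothing in a two-tracer design
identifies it sharply.

### Sampler

Adaptive random-walk Metropolis with three block families per sweep: all
group vectors (independent blocks, vectorized), all individual deviations
(independent blocks, vectorized), and log ω (with the log-scale Jacobian).
Proposal scales adapt toward 30 % acceptance by Robbins–Monro during
burn-in only, so the post-burn-in chain is a fixed Markov kernel. Run-length
presets: `short` (2 chains × 3 000, quick checks), `test` (3 × 20 000, the
desk-scale default used throughout the test suite), `long` (3 × 100 000),
`extreme` (3 × 3 000 000, publication-length runs). Convergence is reported
(split-chain Gelman–Rubin per group-level proportion and ω, Geweke per
chain) and never silently enforced: a failed run still returns its draws
with failure flags.

Degenerate inputs have explicit conventions: K = 1 returns the point
posterior p = 1; sources with identical tracer distributions trigger a
non-identifiability warning (only their summed contribution is meaningful);
a zero mixture variance yields −Inf log likelihood unless the observation
matches the mean exactly.

## Specialization index

`Ɛ = ‖p − g‖₂ / √((K−1)/K)` with `g = (1/K, …, 1/K)`. The normalizing
constant is the only scaling for which a single-source diet maps to exactly
1; the index is linear along rays from g to a vertex, permutation-invariant
and bounded in [0, 1]. Because Ɛ is convex in p, Ɛ(posterior-mean diet) ≤
mean per-draw Ɛ; both are reported, since a dispersed posterior makes them
differ materially. Strategy labels use configurable cut points (defaults:
generalist ≤ 0.34 < specialist-generalist ≤ 0.6 < specialist), boundary
values falling in the less specialized class. K is the number of functional
groups entering the model; Ɛ values computed at different K are not directly
comparable and summaries carry K for that reason.

## Permutation tests and prey aggregation

One-way PERMANOVA partitions squared Euclidean distances directly
(`SS_total = Σ_{i<j} d²/N`, within-group analogue per group) and permutes
group labels; when the number of distinct relabellings does not exceed the
permutation budget the null set is enumerated exhaustively and the p-value
is exact, otherwise the positively biased Monte-Carlo estimator
`(1 + exceedances)/(1 + B)` avoids zero p-values. The two-factor variant
uses marginal (partial) sums of squares on the Gower-centered inner-product
matrix with free permutation of raw observations — the simplest defensible
scheme when no permutation strategy is prescribed; it matches vegan's
marginal tests on crossed designs.

SIMPER defaults to the squared-Euclidean decomposition (per-variable term
`(x_iv − x_jv)²`), consistent with Euclidean PERMANOVA, and conserves the
mean squared between-group distance exactly; classical Bray–Curtis
decomposition is available behind `method = "bray"` for compositional
conventions.

Pairwise PERMANOVA p-values are adjusted by Benjamini–Yekutieli (valid under
arbitrary dependence; delegated to `stats::p.adjust`). Two prey merge into a
functional group when their adjusted p exceeds α *and* their ecology is
declared compatible; functional groups are single-linkage components of that
relation, and a transitive merge that joins a distinguishable pair is
logged, not hidden.

## Clustering and validation

Consumer signatures are z-standardized (the two tracers have different
natural spreads) and clustered with Ward linkage on Euclidean distances —
neither is forced by theory; both are arguments. The number of clusters
maximizes the Dunn index (minimum between-cluster point distance over
maximum within-cluster diameter), ties to the smallest k, all-singleton
partitions excluded, and a best index below 1 — diameters exceeding
separation — raises a weak-structure warning rather than an error, because
overlapping-but-real structure is the normal case in tracer data. Partitions
are validated by leave-one-out linear discriminant accuracy, with a
ridge-regularized fallback when a within-class covariance is singular.

## The synthetic-data generator

`scenario_regime_shift()` encodes the package's default study design: six
prey functional groups pooled (exact moment pooling) from a reference table
of ten taxon × region entries for the Estuary and Gulf of St. Lawrence; a
two-period consumer population (pre: three groups of 10/24/6 whales, post:
two groups of 16/24) whose planted diets span ultra-specialized (89 % on one
group, Ɛ ≈ 0.87) to generalist (Ɛ ≈ 0.15); TDFs as above; analytical noise
0.11/0.12 ‰. Group sizes mirror a realistic decade of biopsy sampling
(~80 animals) and the diet vectors are illustrative of a regime shift, not
ground truth for any real population. Tracers are simulated independently
within a source (only marginal moments are specified; a covariance would be
an invention), dates uniformly within period windows, and fatty-acid
profiles as Dirichlet draws scaled to mass percent.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: tissue turnover dynamics and seasonal integration
windows, spatial movement, lipid dynamics in blubber, non-normal or
covarying source distributions, and prey availability. The generator draws
consumers from the *same* process-error family the model fits, so
recovery tests validate the inference machinery, not the biological
adequacy of the process-error assumption.

## Known limitations, measured

Two structural effects dominate end-to-end accuracy, and both are visible in
the shipped tests rather than hidden:

* **Under-determination at K = 6.** Two tracers give two linear constraints
  per group; with six sources each group diet has a three-dimensional
  likelihood null space resolved only by the prior, which pulls minor
  components toward 1/6. Parameter-recovery guarantees are therefore stated
  and tested at K = 3 (posterior means within ±0.10 of truth at n = 30;
  95 % interval coverage ≈ 94 % across 100 replicates). The end-to-end
  six-source recovery test documents the resulting error (max ≈ 0.17) and
  is expected to exceed a ±0.10 bound; the qualitative period contrast in
  specialization is robust.
* **Cluster-then-fit truncation.** Using value-derived clusters as mixing
  groups truncates within-cluster variance; the process-error likelihood
  responds by evening diets out. Measured on one simulated homogeneous
  group: a single-group fit recovers (0.7, 0.2, 0.1) to max error 0.02,
  while the same data forced through two clusters errs by ≈ 0.13. A
  parametric-bootstrap homogeneity guard was prototyped and rejected for
  lack of power on realistically overlapping groups; the pipeline therefore
  keeps the clustering stage unconditional and reports per-cluster
  diagnostics so the user can judge.

Other defaults: period boundary records fall in the later period; permuted
p-values never report 0; correction coefficients are never hard-coded (an
all-identity model warns loudly); missing fatty-acid columns are
zero-filled and counted, not dropped; the mixing model is fitted per period
(fitting jointly across periods would let one period's clusters absorb the
other's signal through the shared ω).

## Problem sizes

The suite runs the sampler at 3 × 20 000 iterations for the headline
recovery check, 100 × (2 × 3 000) for coverage, 1 000 × 499 permutations
for type-I calibration, and 100 seeded replicates for cluster-selection
power — sizes chosen so the whole suite completes in a few minutes on a
laptop while keeping Monte-Carlo error well below the tolerances tested.
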