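# trophoniche

Dietary-niche inference for marine predators from two-tracer stable isotope
data (δ13C, δ15N) and compositional fatty-acid profiles.

Baleen whales and other large predators cannot be observed feeding at depth;
what they eat must be inferred chemically from tissue biopsies. This package
implements the complete inferential chain used in trophic-ecology studies of
that kind, for ecologists who have consumer tracer values and a table of
candidate prey:

1. **Tracer preparation** — δ-notation conversion, lipid-extraction and
   DMSO-preservation corrections (user-supplied coefficients), selection and
   renormalization of the extended dietary fatty-acid subset.
2. **Prey aggregation** — pairwise PERMANOVA on prey tracer signatures
   (Euclidean distance, permutation p-values, exact enumeration on small
   designs) with Benjamini–Yekutieli adjustment; prey that are statistically
   indistinguishable and ecologically comparable are merged into functional
   groups. SIMPER decomposes between-group dissimilarity into per-variable
   contributions.
3. **Bayesian mixing model** — consumer tracer values are modelled as draws
   from the process-error mixture
   `x_i ~ Normal( Σ_k p_k (μ_ik + λ_i), Σ_k p_k² (σ_ik² + τ_i²) )`,
   where `p` is the diet composition, `μ/σ` the source moments and `λ/τ` the
   trophic discrimination factor (TDF) mean/SD (defaults 1.0 ± 0.5 ‰ for
   carbon, 1.7 ± 0.5 ‰ for nitrogen). Diets are parameterized on isometric
   log-ratio (ILR) coordinates with group fixed effects and individual
   random effects; a flat Dirichlet prior on group diets is induced exactly
   through the ILR Jacobian. Sampling is by adaptive random-walk Metropolis;
   convergence is checked with split-chain Gelman–Rubin and Geweke
   diagnostics.
4. **Individual specialization** — the index
   `Ɛ = ‖p − g‖₂ / √((K−1)/K)`, the normalized Euclidean distance between a
   diet `p` and the ultra-generalist diet `g = (1/K, …, 1/K)`; 0 is an
   ultra-generalist, 1 an ultra-specialist. Computed per posterior draw and
   summarized.
5. **Feeding strategies** — hierarchical clustering (Ward) of consumer
   signatures within time periods, number of clusters chosen by the Dunn
   index, validated by leave-one-out linear discriminant analysis.

A seeded synthetic-data generator (`scenario_regime_shift()`,
`generate_consumers()`, `generate_fa_profiles()`) reproduces the statistical
structure the analysis assumes — prey taxa parameterized from a reference
table for the Estuary and Gulf of St. Lawrence, consumers drawn from the
forward mixing model, Dirichlet fatty-acid profiles — so the entire pipeline
runs without any field data.

## Worked example

Simulate 30 consumers feeding at proportions (0.7, 0.2, 0.1) on three prey
from the reference table, fit the mixing model, and summarize:

```r
library(trophoniche)

srcs <- list(
  source_spec("ArcticKrill",   NA, -18.7, 0.3,  9.3, 0.6,  28),
  source_spec("HerringEst",    NA, -17.9, 0.9, 12.7, 0.6,  40),
  source_spec("NorthernKrill", NA, -19.5, 0.5, 10.7, 0.4, 110))
d <- matrix(c(0.7, 0.2, 0.1), 1)
colnames(d) <- paste0("diet.", sapply(srcs, `[[`, "name"))
groups <- cbind(data.frame(group = "g1", period = "pre", n = 30L),
                as.data.frame(d))
scn <- scenario(srcs, groups, tdf = tdf_spec(), seed = 1)
sim <- generate_consumers(scn)

fit <- fit_mixing_model(sim$consumers, srcs,
                        mixing_config(preset = "test", seed = 1))
summarize_posterior(fit, "group")
#>   unit_type unit_id        source  mean     sd  q2.5 q97.5
#> 1     group      g1   ArcticKrill 0.662 0.0535 0.557 0.770
#> 2     group      g1    HerringEst 0.211 0.0377 0.137 0.284
#> 3     group      g1 NorthernKrill 0.126 0.0557 0.026 0.240

epsilon_posterior(fit)[1, ]
#>   unit_type unit_id eps_mean eps_sd eps_q2.5 eps_q97.5 eps_of_mean_diet K
#> 1     group      g1    0.504 0.0823    0.342      0.667           0.499 3
```

The posterior means recover the planted diet within a few percent of each
proportion, every 95 % interval contains its true value, and all split-chain
R-hat values are below 1.1. The mean per-draw specialization index (0.50) is
slightly below the index of the true diet (0.56) because the index is convex
and posterior spread pulls it toward the generalist value; both the per-draw
summary and the index of the posterior-mean diet are reported.

The full pipeline (simulate → correct → aggregate → cluster → fit →
specialize → report) is one call:

```r
report <- run_pipeline(run_config(scenario = "regime_shift", seed = 1,
                                  out_dir = "out"))
```

or, from a shell, `Rscript scripts/pipeline.R --config run.yaml --seed 1
--out out`. The output directory receives the simulated tables, a
machine-readable `report.json` and a human-readable `report.md`, all stamped
with a fingerprint of the resolved configuration; reruns with the same
configuration and seed regenerate them byte-identically.

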