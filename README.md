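# venomtherm

Analysis of how rearing temperature reshapes the venom of the *Drosophila*
parasitoid *Leptopilina boulardi* and the outcome of its immune interaction
with the host. The package is aimed at researchers analysing 1D-gel venom
profiles and host–parasitoid assay counts: it covers the full chain from lane
densitometry to the identification of temperature-affected venom proteins,
plus the mixed-model statistics for encapsulation outcomes, with a
synthetic-data module that generates design-matched data with ground truth.

## What it computes

**Venom composition (global analysis).** Reference-band peak volumes are
integrated from lane profiles (trapezoid over fixed windows, no background),
normalized by quantile or cyclic-loess normalization, and analysed by:

- **PERMANOVA** on Euclidean distances with sequential sums of squares,
  temperature then replicate, p = (1 + #{F\* ≥ F}) / (1 + N) over N free row
  permutations (default 5000);
- **LDA** after within-replicate centering: Fisher axes from the generalized
  eigenproblem B a = λ W a, scores, temperature centroids;
- a **centroid trend arrow** — the least-squares line through the 20/25/30 °C
  centroids, oriented toward increasing temperature;
- a **Spearman screen** of every band against the arrow scores (Bonferroni
  over bands), then a **UPGMA / partial-correlation screen**: bands cluster
  at distance 1 − |ρ| with a 0.45 correlation threshold, and within each
  cluster a candidate stays *direct* only if its rank-based partial
  correlation with the trend, given the cluster's other candidates, survives
  Bonferroni at 0.05 — otherwise it is *indirect* (merely co-varying);
- annotation of direct bands with their protein content, flagging proteins
  with ≥ 10 peptide matches as abundant.

**Interaction outcomes.** Per-dish dissection counts become binomial
responses (parasitism rate; parasitic success L+LOC vs CC; encapsulation
capacity; inhibition capacity; escape capacity), fitted as logit GLMMs with a
replicate random intercept (`lme4`); if the Pearson overdispersion ratio
exceeds 2, an observation-level random effect is added. Tukey-adjusted
pairwise temperature contrasts via `emmeans`. Oil-drop melanization classes
0–5 are tested for independence from temperature by a Monte-Carlo Fisher
test, and binarized (classes 2–5 = melanized) for a capillary-random-effect
GLMM. Gaussian LMMs (optionally Box-Cox transformed) handle total band
intensity, reporting the temperature F with containment df (F_2,12 in the
balanced 3 × 5 design).

## Worked example

```r
library(venomtherm)

sim   <- simulate_band_matrix(band_sim_spec(seed = 11))  # 105 wasps x 35 bands
trend <- venom_trend(sim$matrix, n_permutations = 5000, seed = 11)
trend
#> PERMANOVA (Euclidean distance, sequential SS, 5000 free permutations)
#>         term  Df SumOfSqs      R2      F p_value
#>  temperature   2    43491 0.34169 28.371   2e-04
#>    replicate   4     8678 0.06818  2.831   2e-04
#>     Residual  98    75113 0.59013     NA      NA
#>        Total 104   127282 1.00000     NA      NA
#> ...
#> 6 of 35 bands correlated with the trend (Bonferroni p < 0.05):
#>   band_5, band_6, band_12, band_13, band_22, band_23

screen_bands(trend)
#> band screen: 3 direct, 3 indirect, 29 unaffected (of 35 bands); 6 screened
#>     band cluster    class sign   rho    p_adj partial_rho partial_p_adj
#>   band_5       5   direct    1 0.902 8.64e-38      0.4247      6.37e-05
#>   band_6       5 indirect    1 0.826 6.60e-26     -0.0120      1.00e+00
#>  band_12       5   direct    1 0.902 6.74e-38      0.5144      2.63e-07
#>  ...
```

Temperature explains 34% of venom-composition variance here (replicates 7%),
and the screen recovers exactly the generator's truth: the three planted
direct bands keep significant partial correlations with the trend
(increasing), while their three mediated copies — marginally just as
correlated (ρ ≈ 0.8) — drop out once their parent band is conditioned on.
Annotating a screen against the shipped band–protein tables
(`inst/extdata/ism_band_proteins.csv`, `isy_band_proteins.csv`) lists the
abundant proteins in each direct band, e.g. the RhoGAP LbGAP (52 peptide
matches) in band 22.

For outcome data:

```r
os  <- outcome_sim_spec(n_dishes_per_temperature = 50,
                        logit_parasitism = c(-1, 0, 1), seed = 2)
rec <- simulate_outcomes(os)
resp <- derive_interaction_responses(rec)
fit <- fit_binomial_glmm(resp[resp$metric == "parasitism_rate", ])
fit$coefficients["temperature30", "Estimate"]   # ~2, the planted 20->30 shift
fit$olre                                        # overdispersion rule fired
```

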