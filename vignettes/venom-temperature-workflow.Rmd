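---
title: "Temperature, parasitoid venom and host immunity: models and methods"
author: "venomtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature, parasitoid venom and host immunity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtherm)
```

## The scientific problem

*Leptopilina boulardi* is a koinobiont parasitoid of *Drosophila* larvae.
Whether a parasitized host survives depends on an arms race between the host's
encapsulation response (layered hemocyte capsules hardened by melanin) and the
immunosuppressive venom the wasp injects at oviposition. Rearing temperature
can shift both sides of this interaction. `venomtherm` implements a complete
analysis chain for two kinds of data:

1. **Venom composition** from 1D SDS-PAGE gels: reference-band intensities per
   individual female (105 per line: 3 rearing temperatures x 5 replicates x 7
   females), normalized, then screened for bands whose intensity changes with
   temperature.
2. **Interaction outcomes** from parasitism assays (dissection categories
   L / LOC / CC, parasitism rates) and from oil-drop injection assays
   (ordinal melanization classes 0-5), analysed with binomial mixed models.

A synthetic-data module generates both kinds of data with known ground truth,
so every stage of the chain can be validated by parameter-recovery and
calibration experiments.

## Densitometry

**Quantification.** A lane is an intensity profile over migration position.
Each reference band is quantified as a *peak volume*: the trapezoidal integral
of the raw profile over a fixed window `nominal_position +/- window_halfwidth`.
No background is subtracted and no per-lane peak re-centering is attempted —
the fixed-window rule is deterministic and testable, and nothing in the study
design requires re-estimation. Window widths are configurable because gel
calibrations differ; the profile simulator defaults to a half-width of 4 peak
standard deviations, which captures > 99.99% of a Gaussian peak's area (the
round-trip tests recover planted volumes to well under 5%).

**Normalization.** Two methods are provided, matching the two line-specific
configurations used in practice:

* `quantile_normalize()` — every lane is forced to share one common intensity
  distribution (the across-lane means of sorted values, assigned by rank; ties
  get the mean of the tied quantiles). Delegates to
  `limma::normalizeQuantiles()`. Applied to raw intensities; the operation is
  idempotent and exact by construction.
* `cyclic_loess_normalize()` — for every pair of lanes a loess curve is fitted
  to M (log2 difference) against A (log2 average) and half the fitted trend is
  removed from each lane, cycling over pairs. Works on `log2(intensity +
  offset)` with `offset = 1` by default (standard for intensity data that can
  touch zero), `span = 0.7` and 3 iterations (the conventional defaults of
  `limma::normalizeCyclicLoess`, exposed as arguments).

One numerical point worth stating: normalization *moves lane means by design*.
What cyclic loess preserves is the A scale — the per-band across-lane mean log2
intensity — and that is the invariant the tests check (to 0.01 log2 units). A
lane that carried a systematic offset will, correctly, not keep its mean.

`total_band_intensity()` (the per-lane sum over reference bands) is the proxy
for the total amount of venom protein.

## The multivariate temperature trend

The global analysis of venom composition runs in five steps, wrapped by
`venom_trend()`:

1. **PERMANOVA** (`permanova()`): Euclidean distances on the band matrix,
   temperature then replicate as ordered factors with sequential (Type I) sums
   of squares, pseudo-F per term, and p-values from freely permuting response
   rows: `p = (1 + #{F* >= F}) / (1 + n_permutations)`, 5000 permutations by
   default. R^2 per term is its share of the total sum of squares. Ties at
   `F* == F` are counted as exceedances using a `sqrt(machine epsilon)`
   tolerance, since permutations of equivalent row assignments reproduce the
   observed statistic only up to rounding. An `exhaustive = TRUE` mode
   enumerates all `n!` permutations for small fixtures; the test suite checks
   it against a brute-force oracle and checks the sampled version against
   `vegan::adonis2`. The Euclidean metric and free permutation scheme are
   deliberate choices: the responses are band intensities (not abundances),
   and free permutation is the reference scheme against which the sequential
   SS decomposition is well defined.
2. **Within-replicate centering** (`center_within_replicates()`): every
   replicate's mean per band is shifted to the grand mean, so gel/batch
   structure cannot drive the discriminant axes. Centering is applied in two
   passes so the postcondition holds to machine precision.
3. **LDA** (`fit_lda()`): Fisher discriminant axes from the generalized
   eigenproblem `B a = lambda W a` (between- vs pooled within-group
   covariance), solved by Cholesky whitening plus a symmetric
   eigendecomposition; axes are scaled to unit pooled within-group variance.
   Bands are not standardized to unit variance first — intensities share a
   scale, and standardization would up-weight noise bands. A ridge of `1e-8 *
   mean(diag(W))` is added by default: quantile normalization gives every lane
   an identical value multiset, hence constant row sums, hence a within-group
   covariance that is rank-deficient by exactly one. The ridge keeps the
   eigenproblem well posed there and perturbs well-conditioned problems below
   reporting precision (the oracle tests run with `ridge = 0`).
4. **Centroid trend arrow** (`centroid_trend_arrow()`): the least-squares line
   through the three temperature centroids in the discriminant plane, as a
   unit direction oriented from the 20 degC centroid toward the 30 degC
   centroid's projection. This is the scalar summary of "venom change with
   increasing temperature".
5. **Band screen** (`band_trend_correlations()`): each individual's *arrow
   score* is the scalar projection of its discriminant-plane score on the
   arrow direction; every band gets a Spearman rank correlation against the
   arrow scores (asymptotic t approximation for p, appropriate at n = 105 and
   robust to ties), Bonferroni corrected over the number of bands. Bands with
   adjusted p < 0.05 are trend candidates and carry the sign of their
   correlation. Constant bands have undefined correlations; they are flagged
   and excluded rather than silently dropped.

## Direct versus indirect bands

Bands can correlate with the trend only because they co-migrate or co-vary
with a truly affected band. `screen_bands()` disambiguates:

* `correlation_distance_tree()` clusters bands by UPGMA on the distance
  `1 - |rho|` (Spearman), so strong correlation of either sign means
  proximity.
* `cut_tree_at_threshold()` cuts at height `1 - 0.45 = 0.55`, the published
  correlation threshold.
* `partial_correlation_screen()`: within every cluster holding at least two
  candidates, each candidate's rank-based partial correlation with the arrow
  scores is computed conditioning on the *other candidate bands of that
  cluster* (clustering uses all bands; conditioning uses co-clustered
  candidates only). The coefficient comes from inverting the Pearson
  correlation matrix of rank-transformed variables — algebraically identical
  to correlating the residuals of rank-regressions, which is how the tests
  cross-check it to 1e-10. P-values are Bonferroni corrected over the number
  of bands screened *in this step* (the smallest defensible family).
  Candidates surviving at adjusted p < 0.05 are `direct`; the rest become
  `indirect`; candidates alone in their cluster stay `direct` with their
  marginal sign; everything else is `unaffected`.

`annotate_abundant_proteins()` joins the classification to a band-to-protein
table and flags proteins with at least 10 mass-spectrometry peptide matches as
abundant. Tables for both lines ship under `inst/extdata/`. Bands #18 and #19
of the ISy line (both dominated by the serpin LbSPNy, with opposite reported
trends) are deliberately kept separate: merging them would average away
exactly the non-monotone behaviour that distinguishes them.

## Outcome statistics

`derive_interaction_responses()` turns per-dish dissection counts into the
binomial responses: parasitism rate (mono + multi vs non-parasitized),
parasitic success (L + LOC vs CC), host encapsulation capacity (LOC + CC vs
L), capsule-inhibition capacity (L vs LOC + CC) and escape capacity (LOC vs
CC). All but the parasitism rate use mono-parasitized larvae only, because
multiple larvae in one host make the outcome uninterpretable; "LL" and "L"
are the same category (a free parasitoid larva alone). Dishes without
mono-parasitized larvae are excluded from the mono-based metrics and listed.

`fit_binomial_glmm()` fits the logit-link binomial mixed model with a
replicate (or capillary) random intercept via `lme4::glmer()`. The Pearson
overdispersion ratio (chi-squared over residual df) is computed on this first
fit; if it exceeds 2 the model is refitted with an observation-level random
effect (OLRE) and flagged — the ratio is always taken from the initial fit so
the decision precedes the remedy. The temperature effect is tested by a
likelihood-ratio test against the model without it; pairwise contrasts come
from `emmeans` marginal means with Tukey (multivariate-normal) adjustment on
the link scale. Complete separation (all successes or all failures — the
"always ~100%" cells that real assays produce) is detected and flagged; when
the likelihood is degenerate a flagged empty fit is returned instead of an
error. Experiment-1 replicates (assay days) and experiment-2 replicates
(starting vials) are both modelled as a single random intercept; nothing in
the data structure distinguishes their variance roles.

`fisher_class_independence()` is the Monte-Carlo test of independence between
melanization classes and temperatures: `n_sim` tables (default 2000) with the
observed margins are drawn by `stats::r2dtable()` and
`p = (1 + #{P(table*) <= P(table)}) / (1 + n_sim)`. It is implemented
directly (rather than through `fisher.test(simulate.p.value = TRUE)`) because
the simulation path must also apply to 2x2 tables, where the MC p can be
validated against the exact conditional p — `fisher.test` silently switches
to the exact test there. `binarize_melanization()` pools classes 2-5 as
"melanized" versus 0-1, grouped by capillary (capillary bore influences drop
size, hence the random effect).

`fit_gaussian_lmm()` handles the total-intensity and Western-blot
relative-intensity responses: `lme4::lmer()` with a replicate random
intercept, optional Box-Cox transform (maximum-likelihood lambda on a grid
from -2 to 2, step 0.01), and the temperature F statistic with
containment-style degrees of freedom: denominator df = number of temperature
x replicate cells minus the number of temperature levels, i.e. 15 - 3 = 12 in
the balanced 3 x 5 design. This is the df pair a cell-mean analysis of the
design yields; Satterthwaite or Kenward-Roger approximations on the
individual-level model instead track the residual stratum (df near 100) and
would overstate the precision of the temperature comparison when replicates
are the experimental unit.

## The synthetic-data generator

`simulate_band_matrix()` emulates the venom-profiling design: 3 temperatures
(20/25/30 degC) x 5 replicates x 7 females, 35 bands, baseline 100 intensity
units. Direct bands gain `effect_size * (T - 25)`; indirect bands equal their
parent direct band plus Gaussian link noise (not scaled copies), so the
partial correlation of an indirect band with the trend given its parent is
zero *by construction* — the screen's ideal behaviour is provable, not just
plausible. Replicate offsets are drawn per replicate x band and shared by the
replicate's individuals; intensities are generated on a linear scale and
clipped at zero, since silver-stain volumes are non-negative.

Default magnitudes (`effect_size = 2` intensity units per degC,
`replicate_sd = 1.5`, `noise_sd = link_noise_sd = 4.5`) were chosen so the
variance decomposition of the simulated matrices matches the study's reported
one — temperature explaining roughly a third of composition variance and
replicates about 6% — with three direct and three mediated bands among 35.
With band variance `effect^2 * var(T) ~ 67` against noise variance `~20`,
planted bands are strong but not degenerate: marginal screens flag them
essentially always, while the partial step must genuinely separate mediated
copies.

`simulate_outcomes()` draws, per dish of 30 larvae, a binomial parasitized
count on the logit scale with a dish-level normal intercept (the
overdispersion source — dish-level, not larva-level, mirroring how replicate
structure inflates binomial variance), splits off multi-parasitized larvae,
and distributes the rest over L/LOC/CC by a baseline-category trinomial model
whose two logits share a second dish-level intercept.
`simulate_melanization()` draws ordinal classes 0-5 from a cumulative-logit
model with capillary random intercepts; capillaries are reused across
temperatures, as in the assay.

**What the generator does not emulate** — and therefore what passing tests do
not establish about real gels: lane-loading and staining differences (the
generator plants intensities on the common post-normalization scale, which is
why the acceptance script computes trend statistics on generator output
directly and validates normalization by its exactness properties), spatial
gel artifacts and band co-migration, non-monotone temperature responses
(e.g. proteins peaking at 25 degC, which the linear-trend screen is known to
miss — the LbSPNm/LbSPNy cases), and correlated band blocks beyond the
planted parent-child pairs.

## Simulation sizes and numerical conventions

The validation suite uses: 500 null datasets (105 x 35, 999 permutations) for
PERMANOVA calibration, with the 95% acceptance band [0.033, 0.071] around the
nominal 0.05; 500 null datasets at 50 dishes per temperature for the GLMM
likelihood-ratio test; 100 seeds for logit-effect recovery (mean absolute
error bounded by 0.4); 50 seeds for screen recovery (direct-band sensitivity
at least 0.8, at most 20% of mediated bands misclassified as direct); and
exhaustive 720-permutation enumeration at n = 6. These sizes give
Monte-Carlo standard errors comfortably below the margins they are checked
against.

Conventions worth knowing: random number streams are always taken from an
explicit `seed` argument; permutation tie handling uses a
`sqrt(.Machine$double.eps)` tolerance; Spearman p-values use the asymptotic
approximation uniformly (`exact = FALSE`), so tied data never switch the
reference distribution; constant bands are flagged (undefined correlation)
and assigned distance 1 in the tree rather than dropped; the Box-Cox lambda
grid is fixed so the transform is reproducible.

## Known limitations

* The linear-trend screen cannot detect bands whose intensity changes
  non-monotonically with temperature; the specific (antibody) analyses exist
  precisely for such proteins.
* The Pearson-ratio OLRE rule is a threshold heuristic; near the threshold
  the model choice, and with it the contrast standard errors, can flip
  between neighbouring datasets.
* Containment df = 12 presumes the balanced 3 x 5 design; unbalanced designs
  get the analogous cells-minus-levels count, which is approximate.
* The PERMANOVA permutation scheme permutes rows freely; restricted
  (within-replicate) permutation would give a different, arguably stricter,
  test of temperature but is not what the sequential decomposition models.
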