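Package: venomtherm
Title: Temperature Effects on Parasitoid Venom Composition and
    Host-Parasitoid Interaction Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how rearing temperature shifts the venom
    protein composition of Leptopilina boulardi parasitoid wasps and the
    outcome of their interaction with Drosophila hosts. Covers 1D gel
    densitometry (reference-band quantification from lane intensity
    profiles, quantile and cyclic-loess normalization), a multivariate
    temperature-trend analysis (within-replicate centering, Euclidean
    PERMANOVA with sequential sums of squares, linear discriminant
    analysis, a centroid-trajectory arrow and per-band Spearman screens),
    a UPGMA/partial-correlation disambiguation of directly versus
    indirectly temperature-affected bands, and binomial or Gaussian mixed
    models for encapsulation outcomes with an observation-level
    random-effect rule for overdispersion, Tukey pairwise contrasts and a
    Monte-Carlo Fisher test. Includes synthetic-data generators that
    reproduce the statistical design of the study (gel lanes, band
    matrices, parasitism assays, melanization scores) with ground-truth
    labels for power and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    limma,
    MASS,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    vegan,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
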