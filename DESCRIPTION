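Package: litterflora
Title: Culture-Based Dam-Litter Microbiota Convergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for culture-based (MALDI-TOF identified)
    bacterial isolation records from dam-litter units sampled around
    parturition. Encodes isolates as binary genus presence/absence
    patterns, builds phi-coefficient (Pearson association of binary
    vectors) distance matrices, tracks within-family heterogeneity
    through time with exact Wilcoxon rank-sum comparisons against
    birth, draws per-family complete-linkage dendrograms, and computes
    per-family two-dimensional scaling ordinations with convex-hull
    polygon areas per time point. Includes a synthetic dam-litter
    dataset generator emulating the study design (family-specific
    genus profiles with time-decaying per-sample noise) so every
    stage runs and is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
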