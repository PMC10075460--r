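Package: plastevol
Title: Multilevel Evolution of Phenotypic Plasticity Under Environmental
    Predictability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and statistical analysis pipeline for studying how
    phenotypic plasticity evolves in response to environmental
    predictability in experimentally evolved microalgal populations.
    Simulates autocorrelated (AR(1)) salinity regimes with controlled
    stationary moments and computes realized predictability (rho squared);
    calls differentially methylated regions from per-cytosine bisulfite
    count tables by pooled Fisher exact tests on non-overlapping 100 bp
    windows; fits per-transcript negative-binomial generalized linear
    models with Wald and likelihood-ratio tests for differential
    expression; performs partial redundancy analysis with adjusted R
    squared and ANOVA-like permutation tests; quantifies multivariate
    plasticity as the Euclidean distance between salinity means and
    regresses it on realized predictability; and tests Gene Ontology term
    over-representation with one-sided Fisher tests. A synthetic-data
    module generates all pipeline inputs with planted ground-truth
    effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    MASS,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
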