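Package: microAssembly
Title: Community Assembly Inference for Host-Associated Microbiomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the balance of deterministic (niche) and stochastic
    (neutral) processes shaping microbial communities from OTU count
    tables. Implements rarefaction bookkeeping, alpha diversity indices
    (observed richness, Chao1, ACE, Shannon, inverse Simpson, Pielou),
    Bray-Curtis based PERMANOVA and ANOSIM, Levins' niche breadth with
    quasiswap permutation nulls for habitat generalist/specialist
    classification, a modified stochasticity ratio (MST) against
    configurable null communities, the Sloan neutral community model with
    bootstrap confidence intervals, Blomberg's K phylogenetic signal with
    permutation tests, a Kruskal-Wallis plus linear-discriminant biomarker
    screen, and shared/exclusive/core OTU partition summaries. A synthetic
    community generator with known assembly regimes, planted generalists
    and specialists, and Brownian host traits provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software
RoxygenNote: 7.3.3
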