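Package: ppisign
Title: Inferring Activating and Inhibiting Effects of Protein
    Interactions from RNAi Phenotype Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers whether a known protein-protein interaction is
    activating or inhibiting from single-gene RNAi knockdown phenotypes
    in high-content imaging screens. Per-cell morphology features are
    extracted from nucleus images, knockdown profiles are compared
    through pairwise descriptors (morphological-class fractions,
    phenotype-maxima time courses, a linear-discriminant performance
    similarity feature and proximity features against reference genes),
    and a stratified ensemble of support vector machines votes on the
    effect of each interaction. Vote thresholds are calibrated to a
    target precision on held-out cross-validation votes. Downstream,
    an Effect Similarity Rate clusters genes by the concordance of
    their predicted effects, and a domain-class pair enrichment
    procedure validates predictions against functional annotation.
    A synthetic screen generator with a tunable phenotype effect size
    supports end-to-end benchmarking without screen images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    EBImage,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Classification, Network,
    SystemsBiology, Clustering
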