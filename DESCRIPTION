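Package: gutperm
Title: Characterization of Gut Metabolites and Prediction of Gut Permanence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation and analysis of compound tables of human gut
    metabolites, serum metabolites and oral drugs, and prediction of in
    vivo gut permanence from molecular structure. Provides structure
    normalization and cross-set deduplication on top of OpenBabel,
    physicochemical descriptors (including an in-package QED
    implementation), Bemis-Murcko scaffold statistics, 2048-bit path
    fingerprints with Tanimoto similarity profiles, pKa-based ionization
    class assignment at configurable gut pH, construction of the
    Gut/Gut-Serum/Serum/DrugBank compartment sets and the Gut
    Lingerer/Traverser permanence labels, a statistical battery
    (Kruskal-Wallis with Conover post hoc, common-language effect sizes,
    Mann-Whitney with Benjamini-Hochberg correction, contingency-table
    adjusted residuals with cell-wise exact tests), reversed Lipinski and
    Veber rule baselines, a from-scratch Super Learner stacking
    classifier with out-of-fold meta-features over nine base learners,
    Butina sphere-exclusion cluster splits, and a synthetic compound
    library generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    e1071,
    jsonlite,
    methods,
    randomForest,
    ranger,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
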