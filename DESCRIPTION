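Package: kinmode
Title: Kinase Inhibitor Binding Mode Classification from Interaction and
    Atom Environment Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-class prediction of kinase inhibitor binding modes
    (type I, I1/2, II) from protein-ligand interaction fingerprints (IFPs)
    and atom environment fingerprints, with random forest models,
    Matthews correlation coefficient and balanced accuracy evaluation,
    permutation-test significance, Shannon entropy-based active learning
    as a diagnostic of representation information content, Gini feature
    importance tracking, and Tanimoto-distance t-SNE embeddings. Includes
    a seeded synthetic cohort generator emulating a KLIFS-style data set
    so the entire pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    Rtsne,
    cluster,
    Matrix,
    jsonlite,
    methods,
    yaml,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
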