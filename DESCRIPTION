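Package: csfpr
Title: Core-Substituent Fingerprints for Similarity Searching and Compound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the core-substituent fingerprint (CSFP), a keyed
    1000-bit 2D molecular fingerprint built from analogue-series-derived
    ring fragments and frequency-ranked substituents. Provides activity
    record curation, systematic exocyclic-bond fragmentation for analogue
    series and core extraction, ring-system decomposition with retained
    hybridization states (model ring fragments), substituent harvesting,
    fingerprint assembly with substructure-closure bit setting, Tanimoto
    similarity searching with k-nearest-neighbor scoring, and a benchmark
    protocol for random forest and Tanimoto-kernel support vector machine
    classification with balanced accuracy, Matthews correlation and related
    metrics. Molecule standardization and comparator fingerprints (MACCS,
    ECFP4) are computed through Open Babel via ChemmineR/ChemmineOB.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    data.table,
    jsonlite,
    kernlab,
    ranger,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
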