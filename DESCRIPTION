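Package: molsplit
Title: Whole-Compound-Domain Fold Splitting for Federated QSAR Data Preparation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic train/test fold splitting of chemical structure
    libraries in the whole compound domain, suitable for federated
    privacy-preserving multi-task QSAR modelling. Implements four split
    methods (keyed SHA-256 hashing of canonical SMILES, locality-sensitive
    hashing on high-entropy ECFP bits, sphere exclusion clustering at a
    Tanimoto distance cutoff, and scaffold-network binning with a three-ring
    preference), molecule standardization and folded circular fingerprints,
    split-quality diagnostics (intra-fold pair fraction by similarity bin,
    per-task data and label imbalance), a synthetic chemical-series
    generator for offline testing, and a federated consistency audit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
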