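Package: clscore
Title: ChEMBL-Likeness Scoring and Uniform Subset Sampling for SMILES Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ChEMBL-likeness score (CLscore), a substructure-frequency
    likeness score for small molecules. Molecules are decomposed into circular
    substructures (molecular shingles) of bond radius 1 to 3, rendered as rooted,
    canonical, aromatic, stereochemistry-free SMILES fragments. Shingle frequencies
    tabulated from a reference corpus of bioactive molecules define per-shingle values
    log10(f); the CLscore of a molecule is the mean shingle value over its unique
    shingles, with unmatched shingles contributing zero. The package builds, persists
    and queries shingle frequency tables with a minimum-occurrence cutoff, scores and
    filters SMILES streams, bins molecules into (heavy atom, stereocenter, heteroatom)
    property triplet bins with merge rules, and draws reproducible uniform samples
    across bins via an iterative even-allocation procedure, as used to carve
    drug-like subsets out of large enumerated chemical libraries. A synthetic fixture
    generator with known shingle statistics makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
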