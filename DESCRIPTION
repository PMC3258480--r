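Package: catkit
Title: Catalytic Toolkit Analysis of Enzyme Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of enzyme complexity from mechanism-level enzyme
    records: catalytic-residue propensities per EC class and role profiles
    across catalytic entity kinds (residues, metal ions, organic cofactors);
    estimation of the number of distinct evolutionary families per EC node
    by single-linkage sequence clustering with profile-based singleton
    merging, and by CATH domain-combination clustering with a
    sequence-identity refinement; classification of domains as catalytic or
    binding, catalytic-unit extraction, domain-architecture census and
    domain-to-EC promiscuity. Includes a synthetic record generator with
    planted family structure, propensity multipliers, role assignments and
    domain architectures, so every estimator can be tested against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
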