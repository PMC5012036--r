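Package: lexinet
Title: Explicit Hybridization Networks from Lexical and Distance Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based inference of explicit hybridization networks.
    A neighbor-joining agglomeration is augmented with a per-step detection
    rule that identifies a putative hybrid (recipient) together with its two
    donors and the hybridization degree attributed to each donor. The degree
    is estimated in closed form by least squares, candidate triplets are
    screened with a four-point-condition reticulation score, and acceptance
    is decided against the squared neighbor-deviation statistic of the
    pending join. The package also provides the character-to-distance
    encodings used with lexical cognate data (presence-absence Hamming
    distances with two missing-data strategies, normalized Levenshtein
    distances between word forms, per-meaning distance matrices), per-meaning
    word-tree construction, PHYLIP square matrix input/output, extended
    Newick output with reticulation edges, and a seeded synthetic-data
    generator (random additive matrices, distance-level hybrid injection,
    and cognate-level hybrid datasets) for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Network, Software
RoxygenNote: 7.3.3
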