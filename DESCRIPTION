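Package: phybeta
Title: Phylogenetic Beta Diversity Metrics, Trait Evolution and
    Functional Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes eight phylogenetic beta-diversity metrics (PhyloSor,
    UniFrac, presence and abundance-weighted nearest-neighbour and pairwise
    distances, and Rao's quadratic entropy D and H) together with classical
    Jaccard and Bray-Curtis dissimilarities, on rooted phylogenies and
    site-by-species tables.  Includes Pagel's lambda branch length
    transformation, uniform random polytomy resolution, Ornstein-Uhlenbeck
    and Brownian trait simulation, Blomberg's K, trait dendrograms, Mantel
    tests, metric correlation and principal component summaries, and a
    synthetic gradient-community generator for benchmarking how phylogenetic
    signal in traits governs the recovery of functional beta diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    phytools,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
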