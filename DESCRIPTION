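Package: crmEvol
Title: Lineage-Specific Selection on Cis-Regulatory Modules via
    Ornstein-Uhlenbeck Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects lineage-specific gains and losses of transcription factor
    binding across a phylogeny. Genomic regions are scored for homotypic motif
    clusters with a forward-algorithm hidden Markov model per position weight
    matrix; the resulting CRM score is treated as a quantitative trait evolving
    along a rooted tree and fitted by maximum likelihood under Brownian motion,
    a single-optimum Ornstein-Uhlenbeck process, and branch-shift Hansen models
    in which a designated clade carries its own trait optimum. Models are
    compared by likelihood-ratio tests and Akaike weights, power is assessed by
    parametric bootstrap (phylogenetic Monte Carlo), and divergent motifs are
    discovered by hypergeometric overlap between experimentally divergent
    region sets and predicted divergent region sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: MotifAnnotation, Phylogenetics, Regression, SequenceMatching
RoxygenNote: 7.3.3
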