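Package: divPulse
Title: Hierarchical ABC Tests of Synchronous Divergence Across a Biogeographic Barrier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogeography of co-distributed taxon
    pairs split by a common barrier. Simulates two-population isolation
    coalescent genealogies under a divergence-pulse hyperprior, computes
    population-genetic summary statistics (within/between nucleotide
    diversity, net divergence, Watterson's theta), and runs hierarchical
    approximate Bayesian computation with rejection sampling and
    local-linear regression adjustment to estimate the number of divergence
    pulses (Psi), the dispersion index of divergence times (Omega), and
    mean divergence time, with threshold Bayes factors comparing
    synchronous versus asynchronous divergence. Includes gene-tree
    screening for the two-population model (reciprocal monophyly,
    paraphyly, polyphyly), conversion of coalescent divergence times to
    calendar years, AICc-ranked general linear models relating divergence
    times to life-history predictors, and a synthetic-data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
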