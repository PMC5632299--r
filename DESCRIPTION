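Package: codonsel
Title: Codon-Model Tests of Positive and Relaxed Selection on Labeled Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Goldman-Yang codon substitution models with branch classes and
    branch-site mixtures, maximum-likelihood fitting by Felsenstein pruning,
    likelihood-ratio tests for episodic positive selection on focal branches
    and for relaxed purifying selection (pooled-branch dN/dS comparisons) with
    Benjamini-Hochberg control, replicated-lineage candidate tallying with
    direction-of-effect sign tests, and gene-set over-representation
    statistics (Fisher, EASE-style, binomial). Includes seeded simulators for
    codon alignments under configurable selection regimes, flight-loss style
    study scenarios, and annotation tables with planted enrichment, so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
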