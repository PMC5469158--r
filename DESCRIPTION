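Package: aasubst
Title: Empirical Amino Acid Substitution Models: Estimation, Likelihood and
    Topology Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for working with general time-reversible amino acid
    substitution models: reading and writing exchangeability matrices in the
    PAML .dat layout, building and normalising instantaneous rate matrices,
    computing alignment log-likelihoods under proportion-invariant plus
    discrete-gamma rate heterogeneity with Felsenstein's pruning algorithm,
    estimating new empirical exchangeability matrices by iterative joint
    maximum likelihood over collections of protein alignments, comparing
    fitted models by per-site log-likelihood and information criteria, and
    quantifying tree-topology disagreement through Robinson-Foulds bipartition
    distances together with a lower bound on the number of incorrect
    bipartitions in the worse of two trees. A sequence simulator generates
    alignment collections under a known model so that every stage of the
    pipeline can be exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
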