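Package: paralogsel
Title: Selection and Divergence Analysis of Duplicated Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular-evolution analysis of gene duplicates from
    in-frame codon alignments: a Goldman-Yang codon substitution likelihood
    engine with branch-partitioned omega models, site-mixture models
    (nearly-neutral, positive-selection, discrete, beta, beta&omega) and
    branch-site models fitted by maximum likelihood; likelihood ratio test
    cascades; Nei-Gojobori counting of synonymous and nonsynonymous
    divergence with sliding-window profiles; Tajima relative rate tests;
    codon-usage bias (effective number of codons) and GC composition
    summaries; synonymous-distance molecular-clock dating of a duplication;
    and a codon sequence simulator with known truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
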