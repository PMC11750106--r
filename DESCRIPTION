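Package: tsabc
Title: Evolutionary and Demographic Inference from Tree-Sequence IBD Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers mutation rate, sequencing-error rate and past and present
    effective population sizes from samples of genome sequences, using
    identical-by-descent (IBD) segments extracted from a succinct tree
    sequence (an encoding of the ancestral recombination graph).  IBD is
    defined by a shared most recent common ancestor node, without a length
    threshold and without requiring absence of recombination.  Provides
    method-of-moments estimators for the case where the true tree sequence
    (with node times) is available, and an approximate Bayesian computation
    engine (rejection sampling with local-linear regression adjustment)
    driven by IBD summary statistics for inference from observed haplotypes.
    Includes a coalescent-with-recombination data generator covering
    constant, exponential, step and piecewise demographic models, with
    sequencing-error injection and optional gene conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with msprime and tskit, used by the
    coalescent simulator back end (found on PATH as 'python' or 'python3').
Config/testthat/edition: 3
RoxygenNote: 7.3.3
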