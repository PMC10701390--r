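Package: sparsegp
Title: Sparse Testing Designs and Multi-Kernel Genomic Prediction for NAM
    Populations
Version: 0.1.0
Authors@R:
    person("sparsegp", "developers", email = "sparsegp@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and evaluating genomic-prediction-based
    sparse testing in multi-environment plant breeding trials. Simulates
    nested association mapping (NAM) populations of recombinant inbred
    lines with a hub parent and three founder ancestry groups, builds
    sparse training-set allocations that trade non-overlapping against
    overlapping lines across environments, optimizes fixed-size training
    samples with an E(S2) supersaturated-design exchange algorithm, fits
    Bayesian multi-kernel GBLUP reaction-norm models with
    genotype-by-environment and family-by-environment interactions by
    Gibbs sampling, and scores within-environment predictive ability and
    phenotyping cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
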