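Package: kdFBG
Title: Fast Bayesian HMM Segmentation of Copy-Number Data by kd-Tree
    Sequence Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments continuous-valued genomic observation sequences
    (arrayCGH / SNP-array log2 ratios) with Gaussian-emission hidden Markov
    models under a full Bayesian treatment.  Provides exact forward-backward
    Gibbs (FBG) sampling with conjugate Normal-Gamma-Dirichlet priors, and a
    fast approximate sampler that compresses each chromosome into
    moment-summarized blocks with a modified kd-tree, samples one state per
    block, and updates parameters from block sufficient statistics.  Includes
    an analytic bound on the mass of the ignored within-block state paths, an
    enumeration oracle validating it, automatic compression-width selection
    by L-method knee detection, simulators for benchmark experiments, and
    CNV-call evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
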