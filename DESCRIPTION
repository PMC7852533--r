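Package: kernmet
Title: Kernel Methods for Genomic Prediction in Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("kernmet", "developers", email = "kernmet@example.org",
           role = c("aut", "cre"))
Description: Whole-genome prediction for multi-environment trials (MET)
    combining additive and dominance marker effects with envirotyping-based
    reaction norms. Relationship kernels among hybrids and among environments
    can be built with a trace-normalized linear kernel (GBLUP), a Gaussian
    kernel with median-scaled bandwidth, or a recursive arc-cosine ("Deep")
    kernel. Five model structures of increasing complexity (main additive,
    additive-dominance, genotype-by-environment interaction, and
    envirotype-informed reaction norms) are fitted with an
    eigen-reparameterized Gibbs sampler using scaled-inverse-chi-squared
    priors on variance components. Includes an envirotyping pipeline
    (phenology-interval percentile summaries, scaling and quality control),
    three cross-validation schemes for untested hybrids, sparse testing and
    new environments, predictive-ability statistics, and a synthetic-data
    generator for maize-like single-cross MET experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
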