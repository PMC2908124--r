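Package: codonbench
Title: Multi-Rate Codon Substitution Models and Random-Model Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Time-reversible codon substitution models on the 61 sense
    codons, ranging from the classical single-rate (SR, one dN/dS ratio)
    model through multi-rate models with K exchangeability classes over
    the 75 one-step amino-acid pairs, up to the fully general 75-rate
    (REV) model. Provides maximum-likelihood fitting on a fixed tree by
    Felsenstein pruning, alignment simulation under any model in the
    family, and a benchmarking protocol that fits ensembles of randomly
    assigned rate-class models and compares them to SR with
    likelihood-ratio tests (with Bonferroni correction) and BIC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
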