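Package: hybridreg
Title: Regulatory Mechanism Classification from Allele-Specific F0/F1 Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies the regulatory mechanism (conserved, cis, trans,
    cis-trans) underlying allele-specific differences in transcription-factor
    binding, chromatin marks and gene expression, from replicate read counts
    at single-nucleotide variants in two parental inbred strains (F0) and
    their F1 hybrids. Negative-binomial models describe parental counts and
    beta-binomial models describe F1 allelic counts; four constrained
    maximum-likelihood fits are compared by BIC at every site. Additional
    stages infer inheritance modes (additive, dominant, over/under-dominant),
    distinguish cis from cis-trans effects at lineage-specific sites,
    quantify the distance decay of coordinated allelic imbalance between
    nearby sites against a resampled null, and integrate class calls across
    regulatory layers. A synthetic-data generator reproduces the full
    generative hierarchy with known ground truth so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
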