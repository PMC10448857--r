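Package: hegscape
Title: Homing Endonuclease Gene Landscapes in Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation and comparative analysis of homing endonuclease genes
    (HEGs) across phage genome communities: HEG calling from protein domain
    evidence with allele-state classification (intact, frameshifted, in-frame
    deleted, fused, absent), gene-neighborhood extraction around each HEG with
    essential-marker classification, seed-and-extend detection of pairwise
    nucleotide identity blocks, HEG-island calling (conserved cargo regions
    bracketed by HEGs), DNA-binding/nuclease domain-architecture bisection with
    intragenic repeat and domain-swap detection, group-I-intron-style splice
    detection from RNA-seq coverage dips, and phage-satellite boundary
    prediction from attachment-site repeats. Includes a synthetic
    phage-community generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
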