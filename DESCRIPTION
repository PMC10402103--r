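Package: piebaldkit
Title: Genetic Dissection of Piebald Plumage Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mapping the genetic architecture of
    piebald (patchy white) plumage in pigeon intercrosses and breed panels:
    pixel-count plumage phenotyping, F2 linkage-map construction with staged
    marker filtering and HMM-based genotype cleaning, single-QTL genome scans
    by Haley-Knott regression with permutation thresholds, a genotype-likelihood
    allele-frequency differentiation (pFST-style) scan with a candidate-SNP
    fixation filter and haplotype-group delineation, conserved-noncoding-element
    detection with transcription-factor binding-site gain/loss analysis, and
    read-depth tandem-duplication calling with copy-specific expression
    classification. Includes a synthetic-data module that plants ground truth
    for every stage, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
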