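Package: pemseqr
Title: Junction Classification for Primer-Anchored CRISPR Editing-Outcome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR-Cas9 editing outcomes at a bait locus from
    primer-extension-mediated (PEM-seq style) junction sequencing reads:
    indels, large deletions, off-target and general chromosomal
    translocations, and AAV vector integrations (buried fragments and
    bait-vector fusions). Ships a truth-labelled synthetic library
    generator, a seed-and-extend local aligner, UMI-based molecule
    deduplication, translocation-hotspot off-target discovery with a
    brute-force enumeration oracle, amplicon indel quantification, and
    the normalization conventions used to report editing efficiency,
    translocation rates and vector-integration rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
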