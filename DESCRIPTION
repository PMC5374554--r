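Package: xenomir
Title: Detection of Dietary Plant miRNAs in Plasma Small RNA-Seq and
    Cross-Kingdom Target Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting exogenous (plant-derived)
    microRNAs in human plasma small RNA sequencing data and inferring their
    candidate human target genes. Includes a ground-truthed synthetic cohort
    simulator, adapter trimming and quality filtering, k-mer-indexed read
    assignment with host exclusion, seed-identity matching (6mer, 7mer-A1,
    7mer-m8, 8mer) against host miRNA catalogs, curated-target transfer,
    nearest-neighbor RNA:RNA duplex minimum-free-energy target-site scanning,
    and hypergeometric gene-set enrichment with Benjamini-Hochberg control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
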