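Package: picocult
Title: Culture Genomics of Non-Axenic Picocyanobacteria
Version: 0.1.0
Authors@R:
    person("Picocult", "Developers", email = "picocult@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-resolved analysis of non-axenic
    picocyanobacterial culture collections: taxonomy-based decontamination
    of genome bins, fragment-based average nucleotide identity (ANI) with
    species (95%) and population (85%) delineation, k-mer seeded read
    recruitment with breadth-of-coverage presence calling, heterotroph
    co-occurrence and heat-tree tabulation, ecotype marker-panel contrasts
    with pigmentation calls and gene-content ordination, and CRISPR-Cas
    subtype/completeness profiling with a Cas1 curation chain. Includes a
    synthetic-data module that simulates cultures, reads, bins and
    annotation tables with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    jsonlite,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
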