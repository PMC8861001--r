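Package: splnet
Title: SPL Gene Family Identification and miR156 ceRNA Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying SQUAMOSA promoter-binding
    protein-like (SPL) transcription factors and their post-transcriptional
    regulation by the miR156 module across developmental stages. Provides
    homology screening (exact local alignment with Karlin-Altschul E-values),
    SBP-domain scanning and splice-isoform deduplication, protein
    physicochemical profiling (molecular weight, theoretical pI, GRAVY,
    instability index), neighbor-joining phylogenies with bootstrap supports,
    FPKM/TPM/RPM count normalization with categorical fold-change binning,
    plant-style penalty-scored miRNA target-site prediction on mRNA, lncRNA
    and circRNA (including back-splice junction handling), and construction
    of ceRNA-miRNA-mRNA regulatory triads gated on shared miRNA response
    elements, expression correlation and differential expression. A
    seed-reproducible synthetic-data generator with planted ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
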