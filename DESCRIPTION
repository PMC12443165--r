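Package: promoscreen
Title: Quantification of Barcoded AAV Promoter Library Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of in vivo promoter biopanning screens that use
    barcoded AAV reporter libraries. Extracts 15-nt barcodes from amplicon
    sequencing reads, counts them per sample, and converts gDNA/cDNA barcode
    proportions together with bulk qPCR expression into normalized
    per-promoter, per-tissue expression values. These are deconstructed into
    efficiency scores (which promoter is strongest within a tissue) and
    specificity scores (where a promoter acts), each scaled to sum to 100.
    Also implements the single-vector validation arithmetic (delta-Ct
    relative expression, ddPCR vector genomes per diploid genome, and their
    ratio), a synthetic-screen generator with known ground truth for
    end-to-end parameter-recovery checks, and reporting helpers (Pearson
    correlation, log-rescaled hierarchical clustering, PCA).
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
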