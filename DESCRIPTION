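Package: therasig
Title: Therapy-Induced Somatic Mutagenesis in Clonally Expanded Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying chemotherapy- and
    radiotherapy-induced somatic mutations in clonally expanded healthy
    adult stem cells. Builds SBS96/DBS78/ID83 mutation catalogs from
    VCF/TSV variant calls with clonal (VAF) filtering, fits a bootstrap
    linear mixed-effects aging null for excess mutation burden, performs
    de novo mutational-signature extraction by non-negative matrix
    factorisation and strict constrained signature refitting, estimates
    per-cycle platinum dose-response, SBS:DBS coupling and 5-FU
    activation heterogeneity, classifies structural-variant footprints
    of radiotherapy, and simulates synthetic cohorts with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    pracma,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
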