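Package: regdiscover
Title: Organ-Wise Discovery of Developmental Transcription Regulators
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Screens transcriptional regulators across multi-organ
    developmental RNA-seq atlases. Provides organ-enrichment calling from
    per-organ mean expression profiles, a perinatal temporal candidate
    filter (mean RPKM and birth/adult expression-ratio criteria),
    outgroup-based evolutionary classification of candidates,
    hypergeometric term over-representation with Benjamini-Hochberg false
    discovery control, ChIP-seq peak co-occupancy with nearest-gene
    assignment and E-box motif scanning across species, cross-species
    expression-window extraction with lifespan normalisation, and seeded
    synthetic-data generators with planted ground truth so the whole
    pipeline can be validated end to end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vctrs,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
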