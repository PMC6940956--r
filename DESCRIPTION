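Package: droughtlight
Title: JIP-Test Fluorescence Analysis and Drought Transcriptomics for Barley
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for dissecting photosynthesis under drought stress
    in barley and other crops: JIP-test analysis of fast (OJIP) chlorophyll-a
    fluorescence transients with relative variable fluorescence and K/J/I band
    differentials; negative-binomial Wald differential-expression calling with
    median-of-ratios normalization and BH/BY false-discovery-rate control; GO
    term enrichment by exact hypergeometric tests; position-weight-matrix
    promoter scanning with exact dynamic-programming p-values; and designation
    of transcription-factor to photosynthesis-gene regulatory pairs. Synthetic
    generators for fluorescence transients, count matrices, promoter sets and
    qPCR plates with recorded ground truth make every stage testable without
    instrument or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
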