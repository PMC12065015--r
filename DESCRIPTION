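Package: translosig
Title: Chromosomal Translocation Signatures from Tumor Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts two-way (reciprocal) chromosomal translocations from
    ISCN-style karyotype strings, builds per-entity frequency spectra over
    the 253 possible whole-chromosome translocation types, and compares
    tumor entities pairwise by the coefficient of determination (R^2) after
    excluding characteristic translocations above a frequency cutoff.
    Includes a Dirichlet-multinomial synthetic cohort generator with known
    signature structure, cutoff sensitivity analysis, frequency-category
    summaries, and a reproducible end-to-end pipeline with tabular outputs.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
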