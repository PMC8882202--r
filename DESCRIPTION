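Package: sdhbcurate
Title: Expert-Style Curation of Germline SDHB Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying germline variants in the
    SDHB tumour-suppressor gene (hereditary paraganglioma/pheochromocytoma).
    Implements a gene-adapted ACMG/AMP criterion engine with tumour-assay
    evidence tiers (loss of heterozygosity, SDHB/SDHA immunohistochemistry,
    SDH enzymatic activity, transcriptomic cluster), a parallel PPGL-specific
    decision-tree classifier, a deterministic two-round consensus stage with
    an expert override ledger, cohort summary statistics, and a synthetic
    cohort generator with known ground-truth classes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    VariantAnnotation,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
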