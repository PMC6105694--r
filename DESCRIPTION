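Package: mihascan
Title: Minor Histocompatibility Antigen Landscape Prediction from Phased Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the landscape of minor histocompatibility antigens
    (MiHAs) for HLA-matched stem-cell transplantation pairs. Builds
    variant-aware diploid proteomes from phased genotypes and coding
    transcripts, extracts 9-mer peptidomes, computes the donor-subtracted
    unique recipient peptide (URP) set with causal-variant provenance,
    evaluates the closed-form allele-frequency mismatch-probability model
    for unrelated and sibling pairs, and filters candidate peptides with
    percentile-calibrated position-specific scoring matrices and a
    two-predictor consensus. Ships a synthetic-data module that simulates
    reference transcripts, Hardy-Weinberg cohorts and sibling pairs so the
    whole pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
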