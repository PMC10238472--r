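Package: psdsig
Title: Postsynaptic Density Proteomic Signatures and Drug Reversal Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed (TMT) peptide-level
    proteomics of the postsynaptic density (PSD) in Alzheimer disease with
    and without psychosis: quality control and normalization (sample
    loading, internal reference scaling against pooled-control channels,
    median normalization), PSD-yield adjustment, peptide-to-protein
    roll-up by z-score averaging with detection and splitting of
    uncorrelated peptides, covariate-adjusted differential abundance with
    empirical-Bayes variance moderation, interaction-network enrichment,
    and signed-signature drug repurposing (knockdown-atlas screening,
    drug-target action alignment, LINCS-style validation, Signed Jaccard
    reversal scoring) with evaluation of drug-treatment experiments.
    Ships a synthetic-data module that generates every pipeline input with
    known ground truth for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
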