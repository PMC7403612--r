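Package: mitosieve
Title: Multi-Evidence Verification of Organellar Proteomes from Fraction-Level Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a verified mitochondrial proteome from fraction-level
    label-free proteomics. Implements peptide-set-subsumption protein
    grouping, target-decoy false discovery rate control, unique-peptide
    label-free quantification with mitochondria/chloroplast and
    mitochondria/whole-cell enrichment ratios, a targeting-prediction
    majority consensus across transcriptome variants, orthology evidence
    against reference mitoproteomes, homology-hit filtering, and
    union-plus-curation integration with per-protein provenance. A
    synthetic-data generator emulates the fractionation experiment
    (tryptic digestion, localization-dependent enrichment, 5'-truncated
    transcriptome variants, reference ortholog tables, decoy scores) so
    the whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
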