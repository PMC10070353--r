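Package: psmpolish
Title: Target-Decoy Validation, PTM Site Assembly, Protein Grouping and
    TMT Quantitation for Peptide-Spectrum Match Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-search interpretation of LC-MS/MS peptide-spectrum match
    (PSM) tables: per-run and per-charge target-decoy FDR autovalidation,
    class-conditional FDR control for rare peptide subsets (novel ORFs,
    variants) by fixed thresholding plus a BCS-by-score grid search,
    variable-modification site localization and site-table assembly with
    cross-plex polishing, parsimony protein grouping with "top uses shared"
    subgroup expansion and two protein-polishing passes, TMT reporter-ion
    isotope-impurity correction (Cramer's rule) with ratio quantitation,
    median aggregation and median/MAD normalization, and an HLA class I/II
    immunopeptidome filter chain with length, motif and nested-set
    summaries. Ships seeded synthetic-data generators with known ground
    truth so every stage can be calibrated and tested without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
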