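Package: pepflow
Title: Peptide Identification Curation, Quantitation, and Targeted Assay
    Generation for Shotgun Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the computational core of a shotgun
    proteomics workflow: ingestion of peptide-spectrum matches (canonical
    CSV, pepXML, protXML), target-decoy false discovery rate estimation and
    filtering, emPAI abundance, reporter-ion (iTRAQ/TMT) and SILAC ratio
    roll-up, label-free report merging with ANOVA and volcano tables,
    phosphosite reporting with Mascot delta scores, pairwise sample
    comparison, spectral library curation with proteome uniqueness mapping,
    and fully automated MRM/SRM transition-list generation.  A synthetic
    data generator with recorded ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
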