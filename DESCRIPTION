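Package: cloniche
Title: Clonal Repertoire Statistics and Spatial Microniche Analysis for
    Neonatal Liver T Cell Tolerance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying early-life T cell education in
    tissue: per-subject T cell receptor (TCR) clonality scoring (R20,
    expanded-clone fraction), classification of clonotypes shared between
    regulatory (Foxp3+) and conventional (Foxp3-) CD4 T cell lineages,
    density-based detection of dendritic cell / T cell microniches in
    in-situ transcriptomics cell maps, whole-slide spatial statistics
    (nearest-DC distance, focus density, parenchymal versus perivascular
    classification), and rank-based differential expression between cells
    inside and outside microniches with false-discovery-rate control. A
    seeded synthetic-data generator produces repertoires and tissues with
    known ground truth so every stage is testable without access to the
    original sequencing or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    methods,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
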