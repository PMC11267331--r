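Package: secretomics
Title: Differential Secretion Analysis for Label-Free Quantification Secretomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of label-free quantification (LFQ) secretome
    experiments from MaxQuant proteinGroups tables: contaminant/decoy/site-only
    filtering, replicate-presence filtering, restriction to secreted proteins
    via Gene Ontology Cellular Component annotation, median centering,
    condition-aware imputation of left-censored missing values from
    down-shifted normal distributions, per-protein Welch tests with
    Benjamini-Hochberg false discovery rate control and hit calling, and
    hierarchical clustering of the z-scored intensity matrix. Includes the
    fold-change arithmetic for targeted assays (multiplex arrays, ELISA, qPCR
    2^-dCt relative expression) and a synthetic-data generator with planted
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
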