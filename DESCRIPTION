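Package: tcx
Title: Time-Course Transcriptomics of Seizure-Induced Hippocampal Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age- and time-dependent differential gene
    expression in the kainic-acid status epilepticus model of mesial temporal
    lobe epilepsy. Implements detection-call presence filtering, per-sample
    median normalization, fold-change and unpaired t-test selection with
    permutation-based SAM-style q-values, composite gene-ontology annotation
    merging with alias resolution, reduction of MAPK signalling into thirteen
    component pathways with co-annotation array plots and regulator-polarity
    classification, qRT-PCR delta-delta-Ct concordance accounting, and a
    synthetic-data generator emulating the two-age, two-treatment,
    five-time-point study design so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
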