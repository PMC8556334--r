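Package: bbbcurate
Title: Curation of Multi-Source Blood-Brain Barrier Permeability Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning heterogeneous, redundant, partially erroneous
    multi-source records of molecular blood-brain-barrier permeability
    (numeric log BB values and binary BBB+/BBB- labels) into a clean,
    deduplicated, provenance-annotated database. Provides structure
    standardization (whitespace repair, salt stripping, charge
    neutralization, element filtering, canonicalization), InChI-based
    identity resolution with a pluggable compound-registry resolver,
    reliability-graded consensus aggregation (groups A-D) for both numeric
    and categorical tracks, molecular-descriptor extension, Lipinski
    Rule-of-5 profiling, technical-validation analytics, and a synthetic
    fixture generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    dplyr,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH); Python with rdkit for the
    independent parse-validation backend
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
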