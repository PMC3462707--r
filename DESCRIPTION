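Package: tbmcore
Title: Decision Core of a Multiple-Template Protein Structure Modeling Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the decision logic of a template-based protein
    structure modeling (TBM) pipeline: difficulty-weighted rescoring of
    homology-search hits, consensus-based multiple-template selection,
    core-region alignment handling (terminus trimming and reattachment),
    representative-model selection from a model ensemble, and detection,
    filtering and grafting of unreliable local regions (ULRs).  Ships native
    implementations of the structural similarity metrics the pipeline needs
    (Kabsch superposition, TM-score, GDT-TS, chi1/chi2 rotamer accuracy) and
    a seeded synthetic-fixture generator so the whole pipeline can be
    exercised without external search or modeling tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
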