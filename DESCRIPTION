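Package: mrpilot
Title: Automated Molecular-Replacement Pipeline Decision Layer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Template-library curation, homologue search and ranking,
    search-model preparation (mixed models, polyalanine, domains,
    multimers, ensembles), refinement-trace scoring (Q factor, solution
    probability, good/marginal/poor classification) and the two classic
    orchestration strategies for automated molecular replacement. The
    molecular-replacement and refinement engines themselves are
    abstracted behind a contract; a seeded simulated engine and a
    synthetic-problem generator make every decision path testable
    without crystallographic software.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
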