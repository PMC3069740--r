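Package: prolims
Title: Sample, Protocol and Construct Tracking for Protein-Production Laboratories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A laboratory information-management core for protein-production
    work in structural biology. Provides a typed data model of samples,
    reusable protocol templates and experiments; construct design with
    Tm-driven primer suggestion and 96-well template/primer plate derivation;
    provenance workflow graphs with Graphviz DOT export and sample history
    reports; biological-complex candidate detection; notebook-scoped access
    control; and a single-file store with bulk XML/JSON export and import. A
    deterministic fixture generator emits synthetic targets and multi-stage
    workflows so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
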