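Package: megbids
Title: Model, Curate and Validate MEG-BIDS Dataset Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for the Brain Imaging Data Structure
    (BIDS) as applied to magnetoencephalography (MEG) recordings. Provides a
    bidirectional filename entity grammar, an indexed in-memory model of a
    dataset tree, typed readers and writers for sidecar JSON and TSV metadata
    (MEG sidecars, coordinate-system documents, channels, events, scans and
    participants tables), resolution of effective metadata under the BIDS
    inheritance principle, fiducial-defined head coordinate frames with rigid
    transforms and unit conversion, a conformance validator with a stable
    registry of coded issues, a manifest-driven curator that organises raw
    vendor recordings (treated as opaque payloads) into a conformant tree,
    and a seeded synthetic-fixture generator with named mutation operators so
    every behaviour is testable without real MEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
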