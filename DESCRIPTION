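Package: tgxcurate
Title: Semi-Supervised Harmonization and Integration of Toxicogenomics Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes messy sample-metadata tables against a controlled
    vocabulary through a three-stage, human-in-the-loop curation pipeline
    (column renaming, duplicate-column resolution, value harmonization),
    integrates multiple curated datasets with a traffic-light consistency
    report, and records every action in a replayable, Good Laboratory
    Practice style audit trail with mandatory justifications. Includes a
    deterministic synthetic-fixture generator for ground-truthed testing and
    a command-line interface for scripted batch curation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
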