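Package: tablesim
Title: Similarity Analysis of Surgical Instrument Table Setups
Version: 0.1.0
Authors@R: person("tablesim", "developers", role = c("aut", "cre"),
    email = "tablesim@example.org")
Description: Quantifies the similarity of surgical instrument table setups
    recorded as instrument positions and orientations on a 1920x1080
    interactive surface. Implements a weighted translational/rotational
    distance with a missing-instrument penalty, pairwise similarity
    matrices, leave-one-out clinic attribution via nearest group mean,
    questionnaire aggregation, a synthetic multi-clinic setup generator
    for validation, and a command-line interface. Setup collections are
    read and written in a documented XML dialect and in CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
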