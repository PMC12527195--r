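Package: bluffbeach
Title: Beach-Function Assessment for Feeder-Bluff Shorelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the ecological and physical function of beaches
    below coastal feeder bluffs under four shoreline-management treatments
    (protect/restore crossed with high/low sediment-supply priority). Aggregates
    raw survey records (wrack quadrats, log lines, snorkel transects, fallout
    traps, low-shore quadrats, vegetation transects) into a 30-metric site table;
    derives geomorphic quantities (relative encroachment, toe-to-MSL slope,
    toe-to-MLLW width) from cross-shore elevation profiles and tidal datums;
    hindcasts fetch-limited deep-water significant wave height and period from
    wind scenarios; computes Folk and Ward grain-size statistics from
    percent-by-class data; scores beach function per treatment on a min-max
    0-1 scale bar; and provides permutation-based community statistics
    (Bray-Curtis dissimilarity, PERMANOVA with restricted permutations,
    chi-squared contingency tests, stratified pairwise mean comparisons).
    Includes a hierarchical synthetic survey generator so the entire pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
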