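Package: herbsynergy
Title: Network Pharmacology of Two-Herb Formulas: ADME Screening,
    Compound-Target Networks, and Ingredient Contribution Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible systems-pharmacology pipeline for dissecting the
    synergy and complementarity of a two-herb formula (Acori Tatarinowii
    Rhizoma plus Codonopsis Radix) against a disease target set. Implements
    ADME-based active-ingredient screening (oral bioavailability and
    Tanimoto drug-likeness thresholds with a bioactivity rescue whitelist),
    herb-versus-herb physicochemical property comparison, construction and
    summary of compound-target, target-pathway, and compound-target-organ
    networks, a degree-based per-ingredient contribution score with herb
    subtotals, hypergeometric over-representation analysis with step-down
    and step-up multiple-testing correction, and maximum-expression organ
    assignment. Ships transcriptions of the published active-ingredient and
    disease-target tables plus a seeded synthetic-data generator so every
    stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
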