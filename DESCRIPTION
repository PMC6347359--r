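Package: synletScreen
Title: Synthetic-Lethality Guided Screening of Drug Combinations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a human synthetic-lethal (SL) gene-pair resource from
    yeast double-knockout genetic-interaction screens via multi-source
    ortholog mapping, extends it with a network-feature random-forest
    classifier (annotation Dice coefficients, node centralities, shortest
    paths on a human gene-interaction network), and screens clinical-trial
    drug combinations against the combined SL set: flagging tested
    combinations whose two drugs target the two partners of an SL pair,
    proposing novel such combinations, and ranking them by per-gene
    literature annotation degree. Includes a seeded synthetic-data
    generator that emits every pipeline input with planted SL signal for
    benchmarking and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
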