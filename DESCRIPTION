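Package: zooprior
Title: Collaborative Prioritization of Zoonotic Diseases by AHP and
    Weighted Decision-Tree Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scriptable implementation of the One Health zoonotic disease
    prioritization workflow: stakeholder criteria are ranked by the Analytic
    Hierarchy Process (pairwise-comparison matrices, principal-eigenvector
    priorities, consistency ratios, group aggregation), ranked criteria
    receive sequential integer weights, and diseases are scored through a
    weighted decision tree driven by categorical (binomial or ordinal
    multinomial) questions, then summed, normalized against the maximum
    total, and ranked. Includes validated plain-text input/output dialects
    (YAML configuration, CSV judgments and answers), seeded synthetic-data
    generators for rank-recovery and robustness experiments, a leave-one-out
    criterion sensitivity scan, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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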