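Package: mwisaco
Title: Hybrid Graph-Filter and Ant Colony Gene Selection for
    High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage gene selection for multi-class classification of
    high-dimensional expression matrices. Stage one builds a
    gene-similarity graph (vertices weighted by Fisher scores, edges
    where absolute Pearson correlation exceeds a threshold) and filters
    it with a greedy maximum-weight independent set heuristic, removing
    redundant genes while keeping relevant ones. Stage two refines the
    candidate set with a binary-path ant colony optimization wrapper
    whose fitness is leave-one-out accuracy of a fold-normalized
    1-nearest-neighbor classifier penalized by subset size, plus a
    Fisher-score-biased add/delete local search and a deletion-only
    backward generation step. Includes a synthetic expression-data
    generator with planted informative genes, correlated redundant
    blocks, and noise genes, and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
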