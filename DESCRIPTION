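Package: mechrag
Title: Knowledge-Graph Retrieval-Augmented Generation Benchmarks for Drug
    Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mechanistic question-answer benchmarks from curated
    drug-to-disease mechanism-of-action path records, grounds language-model
    prompts in knowledge-graph evidence retrieved through TRAPI-style
    one-hop queries and verbalized as declarative context statements, prunes
    context by embedding cosine-similarity percentiles, and evaluates paired
    inference runs with exact-match and semantic-concordance metrics,
    McNemar tests, Wilcoxon signed-rank tests, Cliff's delta effect sizes,
    bootstrap confidence intervals, and threshold-sensitivity tables.
    Ships deterministic offline stand-ins (synthetic path database, mock
    TRAPI transport, hash embedder, scripted generation backend) so the
    entire pipeline runs reproducibly without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
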