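Package: colexnet
Title: Inference and Analysis of Full and Partial Colexification Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers full, affix, and overlap colexification networks from
    multilingual segment-annotated wordlists. Word forms are modelled as
    sequences of sound tokens; affix colexifications (one word recurring as
    prefix or suffix of another) and overlap colexifications (two words
    sharing a peripheral substring without a part-of relation) are detected
    per language by associative-array indexing over affix candidates, then
    aggregated into annotated weighted concept graphs. Includes weighted
    degree distributions, Spearman rank comparison of degree vectors,
    subgraph extraction, community detection, exporters (GML, GraphML,
    JSON, TSV), and a synthetic-lexicon generator with planted compounding
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    stringi
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
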