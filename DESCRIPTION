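Package: litkg
Title: On-the-Fly Biomedical Knowledge Graphs from Literature Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds labeled, weighted biomedical knowledge graphs directly
    from collections of input texts. Entity mentions are linked with a
    gazetteer over a user-supplied lexicon and optionally merged with
    PubTator-format annotations; verbal relations between entity pairs are
    extracted per sentence from token/part-of-speech/dependency structures;
    edges are scored with TF-IDF relevance, a biological-verb similarity
    ('bio') based on normalized edit distance, and an ambiguity penalty
    equal to the number of actions on the label; nodes are ranked by
    personalized PageRank with query entities as teleport nodes. A
    graph-retrieval module enumerates and scores evidence paths between
    user-selected entities and assembles a citation-bearing prompt payload
    for an external language-model client. Includes a deterministic
    synthetic-corpus generator with gold annotations, NER and gene-disease
    association evaluation harnesses, and GraphML/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
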