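---
title: "Building and scoring literature knowledge graphs with litkg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring literature knowledge graphs with litkg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkg)
```

## The problem and the pipeline

`litkg` turns a corpus of biomedical texts into a labeled, weighted
knowledge graph and retrieves citation-backed evidence from it. The
pipeline has four stages, each exposed as ordinary functions:

1. **Entity linking.** A gazetteer built from a user-supplied lexicon
   (`entity_lexicon()`, `build_gazetteer()`, `annotate()`) finds entity
   mentions by case-insensitive, longest-match, token-boundary-aligned
   dictionary lookup. Mentions from an external annotator in PubTator
   format can be merged in (`read_pubtator()`, `merge_annotations()`).
2. **Parsing.** Documents are split into sentences and each sentence is
   tokenized, part-of-speech tagged and given a dependency tree through
   a pluggable engine contract (`parse_sentence()`,
   `register_parser_engine()`).
3. **Relation extraction.** For each sentence and each pair of mentions
   of distinct entities, the verbal *actions* connecting them become a
   candidate edge (`extract_relations()`); pairs without an action yield
   no edge — co-occurrence alone is not treated as a relation.
4. **Scoring and assembly.** Candidates with the same (source, target,
   label) merge into one edge with aggregated sentence provenance;
   edges are scored by TF-IDF, bio and ambiguity; nodes by personalized
   PageRank (`assemble_graph()`, `personalized_pagerank()`).

On top of the graph, the retrieval module (`enumerate_paths()`,
`select_paths()`, `build_prompt()`, `graph_rag()`) selects evidence
paths between user-chosen entities and assembles a prompt whose every
sentence carries a resolvable citation key.

## Offsets and containers

All character offsets are 0-based half-open intervals over Unicode code
points, the PubTator convention; a mention's surface always equals the
text slice it indexes, and this is asserted by the readers. Mentions are
plain data frames; the graph is a list of node and edge data frames with
list columns for actions and provenance — printable, subsettable and
directly exportable to GraphML or JSON (`write_knowledge_graph()`; the
JSON form round-trips exactly, GraphML carries everything except
sentence provenance).

## The parser contract and the bundled engine

Relation extraction only needs tokens, PoS tags, head indices and
dependency relations, so parsing is a *contract*: any function that maps
a sentence to that structure can be registered as an engine and selected
by name. The bundled engine is deliberately rule-based and deterministic:

- tokens are alphanumeric runs (internal hyphens/apostrophes allowed)
  plus single punctuation marks;
- a token is tagged `VERB` iff one of its de-inflected forms — the token
  itself, or the token minus `-s`/`-es`/`-ies`, `-ed`, `-ing` with
  silent-`e` restoration and final-consonant undoubling — appears in the
  biological verb-form lexicon;
- the dependency tree is a **verb chain**: the first verb is the root,
  each later verb attaches to the previous one (mirroring how
  coordinated predicates attach in treebank practice), and every other
  token attaches to the nearest preceding verb (or the first verb, or
  token 0 in verbless sentences).

The verb-chain shape is a deliberate design choice over the simpler
"all tokens attach to the first verb" star: with a star tree, the tree
path between two mentions flanking several coordinated verbs contains
only the first verb, so the dependency-mode and surface-mode extractors
would disagree on exactly the multi-verb sentences the ambiguity score
exists for. With the chain, the path between a mention before the first
verb and a mention after the last verb traverses every verb, and the two
modes agree on both worked examples below.

Sentence splitting is rule-based (`.!?` followed by whitespace and an
alphanumeric, with an abbreviation whitelist and an internal-period
guard). A terminator may be followed by a lowercase letter because
biomedical entity names frequently open sentences in lowercase (p53,
circPIP5K1A); the cost is occasional over-splitting after unlisted
abbreviations, which at worst suppresses a cross-boundary candidate
edge.

A statistical parser could be plugged in with
`register_parser_engine("production", fn)` and selected per call;
nothing downstream changes.

## Worked examples

A single action between two mentions labels the edge with that verb:

```{r fig1a}
lex <- entity_lexicon(entity_id = c("G1", "D1"),
                      name = c("TP53 expression", "colon cancer"),
                      category = c("gene", "disease"))
verbs <- verb_lexicon(c("increase", "inhibit"))
doc <- document("d1", "TP53 expression increased in colon cancer.")
g <- build_knowledge_graph(corpus(list(doc)), lex, verbs,
                           mode = "dependency")
g$edges[, c("source", "target", "label", "ambiguity", "bio", "weight")]
```

When intervening mentions go unannotated, several verbs pile up between
the two detected mentions; all of them label the edge and the ambiguity
penalty divides its weight:

```{r fig1b}
lex2 <- entity_lexicon(entity_id = c("G4", "D1"),
                       name = c("circPIP5K1A", "colon cancer"),
                       category = c("gene", "disease"))
verbs2 <- verb_lexicon(c("attenuate", "reduce", "facilitate"))
doc2 <- document("d2", paste(
  "circPIP5K1A overexpression attenuates cell viability,",
  "reduces cell motility, and facilitates colon cancer progression."))
g2 <- build_knowledge_graph(corpus(list(doc2)), lex2, verbs2)
g2$edges[, c("label", "ambiguity", "weight")]
```

## Scoring choices

**TF-IDF.** `tfidf_raw(tf, df, n)` is
`(1 + ln tf) · (ln((1 + n)/(1 + df)) + 1)`: log-scaled term frequency,
add-one-smoothed inverse document frequency. `tf` counts supporting
*sentences* (finer-grained than documents and meaningful within a single
paper); `df` counts supporting documents. The smoothing keeps a
single-document corpus — a common use case, one uploaded paper — from
collapsing to all-zero weights. Raw scores are min–max normalized to
[0, 1] per graph so the weight product is well-scaled against bio; a
degenerate all-equal raw vector (including a one-edge graph) normalizes
to 1.

**bio.** Each action is compared with every lexicon verb form by
normalized Levenshtein distance (`distance / max length`, case-folded),
and the action's similarity is one minus the best match; the edge's bio
is the mean over its actions. bio is a *similarity*: the weight
multiplies by it, so verb-like labels must score high and arbitrary
tokens low. Multi-action labels are scored per action and averaged
rather than editing against the concatenated string, whose sheer length
would inflate distances spuriously.

**ambiguity and weight.** Ambiguity is the action count;
`edge_weight(t, b, a) = t · b / a` exactly. Weight is strictly
increasing in TF-IDF and bio on (0, 1] and strictly decreasing in
ambiguity, which the tests assert.

**Personalized PageRank.** Power iteration on transitions proportional
to outgoing edge weights; the teleport vector is uniform over the query
nodes (over all nodes when none are given); dangling-node mass is
redistributed to the teleport vector; a node whose out-edges all have
zero weight transitions uniformly over its out-neighbours. Defaults:
damping 0.85, L1 tolerance 1e-9, at most 200 iterations — the residual
contracts by the damping factor per step, so 0.85^k must undercut the
tolerance, which needs ~130 iterations; 200 leaves headroom, and
non-convergence is an error carrying the residual, never a silent
return. As damping approaches 0 the scores converge to the teleport
distribution, a property used as a test.

## Retrieval (Graph-RAG)

"All paths" between selected nodes is bounded to keep enumeration
tractable: simple paths only, on the undirected view that collapses
parallel edges to the max-weight edge per pair, with defaults
`max_len = 4` edges, `max_paths = 25` per pair and a selection budget of
10 paths. A path's score is the arithmetic mean of its edge weights.
Selection is greedy maximum coverage: take the best-scoring path for
each still-uncovered pair, then spend any remaining budget by descending
score; ties break lexicographically on the node-id sequence, making the
result independent of input order (tested). Evidence sentences are the
provenance of the selected paths' edges, deduplicated, each tagged
`[doc_id:sentence_index]`; an empty selection produces an explicit
no-evidence payload. The recorded generation temperature is 0, and the
bundled client just renders the payload, so no network access ever
occurs in tests or examples.

## The synthetic corpus generator

`generate_corpus()` emulates the one regime the pipeline is designed
for: short declarative biomedical sentences with dictionary-resolvable
mentions. Sentences are templated —
`"<source> <verb+s> <target> in this experiment."` — with two controlled
complications: *distractor* sentences containing neither lexicon terms
nor verb forms (screened programmatically at generation time), and
*multi-verb* sentences that interpose unannotated noun phrases between
three inflected verbs, reproducing the missing-annotation situation that
motivates the ambiguity penalty. Occurrences are assigned to documents
uniformly at random; all draws come, in documented order, from R's
default Mersenne–Twister stream seeded once, so a seed fixes the corpus
byte for byte. Gold mentions and triples are recorded with exact offsets
by construction.

What passing on synthetic corpora does **not** show: robustness to real
biomedical prose — passives ("is increased by"), negation ("does not
inhibit", a known limitation: the negator is not a verb and is silently
dropped), nominalizations ("inhibition of"), anaphora, cross-sentence
relations (never extracted, by design), or entity variation beyond the
lexicon's explicit synonyms. Those require a statistical parser engine
and a richer lexicon, both of which plug into the same contracts.

Default study sizes used by the tests and the acceptance script — 20
documents, 10 planted triples at 2 occurrences each, 30% distractor
rate where noise is wanted — are small enough to run in seconds yet
large enough that every planted pair appears in several documents,
exercising the TF-IDF document-frequency term.

## Degenerate inputs and numerical corners

- Empty corpora, lexicons and verb files are errors at read time;
  an empty candidate set assembles to a valid empty graph that still
  exports and round-trips.
- Two empty strings have edit distance 0 by convention; a comparison
  with an empty string scores the maximum 1.
- Min–max normalization of an all-equal vector returns 1 for every
  edge rather than 0/0.
- Gazetteer key collisions (one surface form, two entities) resolve to
  the lexicographically smallest entity id with a warning — determinism
  over silent nondeterminism.
- Mentions at equal spans from two annotators keep the
  higher-priority source and set a `merged` flag; overlapping unequal
  spans keep the longer one.
- PubTator records whose annotation offsets fall outside the
  title-plus-abstract concatenation, or whose stated surface disagrees
  with the text slice, fail loudly with the offending line.

## Known limitations

Dictionary linking cannot disambiguate context-dependent mentions or
abbreviations; relation direction uses a subject-side heuristic in
dependency mode and text order otherwise, so passives invert direction;
the rule-based engine's verb chain is a crude approximation of real
syntax and over-connects coordinated clauses; and the bio score depends
entirely on the quality of the supplied verb-form list.
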