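# End-to-end pipeline: corpus -> mentions -> candidate edges -> scored
# knowledge graph.

#' Build a knowledge graph from a corpus
#'
#' Runs the full pipeline: gazetteer annotation of every document,
#' optional merging with externally supplied annotations (e.g. PubTator),
#' per-sentence relation extraction, and graph assembly with TF-IDF /
#' bio / ambiguity scoring and uniform-teleport PageRank.
#'
#' @param corpus A `litkg_corpus`.
#' @param lexicon An [entity_lexicon()].
#' @param verbs A [verb_lexicon()].
#' @param mode Relation extraction mode, `"surface"` or `"dependency"`.
#' @param engine Parser engine name.
#' @param external_mentions Optional mention data.frame from another
#'   annotator, merged with the gazetteer output via
#'   [merge_annotations()].
#' @param priority Source priority for merging (highest first).
#' @param include_isolated Keep linked entities without edges as
#'   isolated nodes.
#' @return A `knowledge_graph`.
#' @examples
#' lex <- entity_lexicon(entity_id = c("G1", "D1"),
#'                       name = c("TP53 expression", "colon cancer"),
#'                       category = c("gene", "disease"))
#' verbs <- verb_lexicon(c("increase", "inhibit"))
#' doc <- document("d1", "TP53 expression increased in colon cancer.")
#' g <- build_knowledge_graph(corpus(list(doc)), lex, verbs)
#' g$edges[, c("source", "target", "label", "ambiguity")]
#' @export
build_knowledge_graph <- function(corpus, lexicon, verbs,
                                  mode = c("surface", "dependency"),
                                  engine = "fallback",
                                  external_mentions = NULL,
                                  priority = c("pubtator", "gazetteer"),
                                  include_isolated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "litkg_corpus"))
  if (corpus$n_docs < 1L) stop("corpus is empty", call. = FALSE)
  gaz <- build_gazetteer(lexicon)
  mention_sets <- lapply(corpus$documents, annotate, gaz = gaz)
  mentions <- do.call(rbind, c(mention_sets, list(empty_mentions())))
  if (!is.null(external_mentions) && nrow(external_mentions) > 0L) {
    mentions <- merge_annotations(mentions, external_mentions,
                                  priority = priority)
  }
  cand_sets <- lapply(corpus$documents, function(doc) {
    extract_relations(doc, mentions, verbs, mode = mode, engine = engine)
  })
  candidates <- do.call(rbind, c(cand_sets, list(empty_candidates())))
  rownames(candidates) <- NULL
  assemble_graph(candidates, corpus, verbs, lexicon = lexicon,
                 mentions = mentions, include_isolated = include_isolated)
}
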