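# Candidate edge extraction: the verbal actions connecting each pair of
# entity mentions within a sentence become a labeled candidate edge.
#
# An "action" is a VERB token mediating the relation between two mentions:
# in dependency mode, the verbs on the tree path between the mention head
# tokens; in surface mode, the verbs lying strictly between the two
# mention spans. Pairs with no action yield no edge (co-occurrence alone
# is not a relation). Negation is not specially handled: a negator is not
# a verb and is dropped from the label (known limitation).

empty_candidates <- function() {
  df <- data.frame(source_id = character(), target_id = character(),
                   source_surface = character(), target_surface = character(),
                   source_category = character(), target_category = character(),
                   label = character(), doc_id = character(),
                   sentence_index = integer(), sentence_text = character(),
                   stringsAsFactors = FALSE)
  df$actions <- list()
  df
}

empty_provenance <- function() {
  data.frame(doc_id = character(), sentence_index = integer(),
             sentence_text = character(), stringsAsFactors = FALSE)
}

# The head token of a mention: the token inside the mention span whose
# syntactic head lies outside the span (the last such token, the usual
# noun-phrase head position).
mention_head_token <- function(parse, mention) {
  tk <- parse$tokens
  inside <- which(tk$start < mention$end & tk$end > mention$start)
  if (length(inside) == 0L)
    stop("mention [", mention$start, ",", mention$end,
         ") has no tokens in sentence ", parse$sentence_index, " of ",
         parse$doc_id, call. = FALSE)
  heads_in <- (tk$head_index[inside] + 1L) %in% inside &
    tk$head_index[inside] != tk$index[inside]
  cand <- inside[!heads_in]
  if (length(cand) == 0L) cand <- inside
  cand[length(cand)]
}

tree_path_tokens <- function(parse, i, j) {
  tk <- parse$tokens
  anc <- function(k) {
    out <- k
    while (tk$head_index[k] + 1L != k) {
      k <- tk$head_index[k] + 1L
      out <- c(out, k)
    }
    out
  }
  a1 <- anc(i); a2 <- anc(j)
  lca <- intersect(a1, a2)[1L]
  c(a1[seq_len(match(lca, a1))], rev(a2[seq_len(match(lca, a2) - 1L)]))
}

#' Actions on the dependency path between two mentions
#'
#' Returns the VERB tokens lying on the unique undirected tree path
#' between the syntactic head token of `m1` and that of `m2`, ordered by
#' surface position.
#'
#' @param parse A `sentence_parse` covering both mentions.
#' @param m1,m2 One-row mention data.frames with document-level offsets.
#' @return data.frame with columns `token_index` (0-based), `surface`,
#'   `lemma` (possibly zero rows).
#' @export
extract_actions_dependency <- function(parse, m1, m2) {
  stopifnot(inherits(parse, "sentence_parse"),
            nrow(m1) == 1L, nrow(m2) == 1L)
  if (m1$start == m2$start && m1$end == m2$end)
    stop("m1 and m2 are the same mention", call. = FALSE)
  for (m in list(m1, m2)) {
    if (m$start < parse$start || m$end > parse$end)
      stop("mention [", m$start, ",", m$end, ") outside sentence span [",
           parse$start, ",", parse$end, ")", call. = FALSE)
  }
  h1 <- mention_head_token(parse, m1)
  h2 <- mention_head_token(parse, m2)
  path <- tree_path_tokens(parse, h1, h2)
  tk <- parse$tokens
  v <- sort(path[tk$pos[path] == "VERB"])
  data.frame(token_index = tk$index[v], surface = tk$surface[v],
             lemma = tk$lemma[v], stringsAsFactors = FALSE)
}

#' Actions between two mentions by surface position
#'
#' Deterministic fallback extractor: all VERB tokens (as tagged by
#' [fallback_parse()]) lying strictly between the two mention spans, in
#' order. `m1` must precede `m2`.
#'
#' @param sentence_text Sentence string.
#' @param m1,m2 One-row mention data.frames; offsets are document-level
#'   when `char_offset` gives the sentence's document offset.
#' @param verbs A [verb_lexicon()].
#' @param char_offset Document-level offset of the sentence start.
#' @return data.frame with columns `token_index`, `surface`, `lemma`.
#' @export
extract_actions_surface <- function(sentence_text, m1, m2, verbs,
                                    char_offset = 0L) {
  stopifnot(nrow(m1) == 1L, nrow(m2) == 1L)
  if (spans_overlap(m1$start, m1$end, m2$start, m2$end))
    stop("overlapping mentions", call. = FALSE)
  if (m1$start > m2$start)
    stop("m1 must precede m2 in the text", call. = FALSE)
  parse <- fallback_parse(sentence_text, verbs, char_offset = char_offset)
  actions_between(parse, m1, m2)
}

# VERB tokens of `parse` strictly between the (earlier, later) spans.
actions_between <- function(parse, m1, m2) {
  tk <- parse$tokens
  sel <- which(tk$pos == "VERB" & tk$start >= m1$end & tk$end <= m2$start)
  data.frame(token_index = tk$index[sel], surface = tk$surface[sel],
             lemma = tk$lemma[sel], stringsAsFactors = FALSE)
}

#' Build an edge label from actions
#'
#' One action labels the edge with its surface form; several actions are
#' concatenated in sentence order, separated by `"; "` so the individual
#' actions stay recoverable for bio scoring.
#'
#' @param actions Character vector of action surfaces, or the data.frame
#'   returned by the extractors.
#' @return The edge label string.
#' @export
build_edge_label <- function(actions) {
  if (is.data.frame(actions)) actions <- actions$surface
  if (length(actions) == 0L)
    stop("cannot build an edge label from zero actions", call. = FALSE)
  paste(actions, collapse = "; ")
}

#' Extract candidate edges from a document
#'
#' For each sentence, every unordered pair of mentions with distinct
#' entities and at least one action yields one candidate edge. Direction:
#' in dependency mode the mention on the subject side of the first action
#' (an `nsubj`-like relation to it) is the source; when undecidable, and
#' always in surface mode, the earlier mention is the source.
#'
#' @param doc A [document()].
#' @param mentions Mention data.frame for `doc` (non-overlapping spans).
#' @param verbs A [verb_lexicon()].
#' @param mode `"surface"` or `"dependency"` (config key
#'   `relations.mode`).
#' @param engine Parser engine for sentence parsing.
#' @return A candidate-edge data.frame: `source_id`, `target_id`,
#'   surfaces, categories, `label`, `actions` (list column), `doc_id`,
#'   `sentence_index`, `sentence_text`.
#' @export
extract_relations <- function(doc, mentions, verbs,
                              mode = c("surface", "dependency"),
                              engine = "fallback") {
  mode <- match.arg(mode)
  stopifnot(inherits(doc, "litkg_document"))
  mentions <- mentions[mentions$doc_id == doc$doc_id, , drop = FALSE]
  if (nrow(mentions) < 2L) return(empty_candidates())
  parses <- parse_document(doc, verbs, engine = engine)
  subj_rels <- c("nsubj", "nsubjpass", "nsubj:pass", "csubj", "csubj:pass")
  rows <- list()
  for (p in parses) {
    sm <- mentions[mentions$start >= p$start & mentions$end <= p$end, ,
                   drop = FALSE]
    if (nrow(sm) < 2L) next
    sm <- sm[order(sm$start), , drop = FALSE]
    sent_text <- paste(  # sentence slice from the document text
      slice_text(doc$text, p$start, p$end))
    for (i in seq_len(nrow(sm) - 1L)) {
      for (j in seq(i + 1L, nrow(sm))) {
        mi <- sm[i, , drop = FALSE]
        mj <- sm[j, , drop = FALSE]
        if (mi$entity_id == mj$entity_id) next
        acts <- if (mode == "dependency") {
          extract_actions_dependency(p, mi, mj)
        } else {
          actions_between(p, mi, mj)
        }
        if (nrow(acts) == 0L) next
        # orientation: subject-side mention of the first action, else earlier
        src <- mi; tgt <- mj
        if (mode == "dependency") {
          a1 <- acts$token_index[1L] + 1L
          tk <- p$tokens
          hi <- mention_head_token(p, mi)
          hj <- mention_head_token(p, mj)
          subj_i <- tk$head_index[hi] + 1L == a1 && tk$deprel[hi] %in% subj_rels
          subj_j <- tk$head_index[hj] + 1L == a1 && tk$deprel[hj] %in% subj_rels
          if (subj_j && !subj_i) { src <- mj; tgt <- mi }
        }
        row <- data.frame(
          source_id = src$entity_id, target_id = tgt$entity_id,
          source_surface = src$surface, target_surface = tgt$surface,
          source_category = src$category, target_category = tgt$category,
          label = build_edge_label(acts$surface), doc_id = doc$doc_id,
          sentence_index = p$sentence_index, sentence_text = sent_text,
          stringsAsFactors = FALSE)
        row$actions <- list(acts$surface)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
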