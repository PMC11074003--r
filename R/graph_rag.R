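# Graph-based retrieval-augmented generation: enumerate and score the
# simple paths connecting user-selected entities, pick a
# coverage-maximizing subset, and assemble a citation-bearing evidence
# prompt for an external LLM client. The LLM call itself is behind a
# client interface; the bundled client is a no-op that renders the
# payload verbatim, so nothing here touches the network.

#' Enumerate evidence paths between selected nodes
#'
#' For each unordered pair of selected nodes, all simple paths of at most
#' `max_len` edges on the undirected collapsed view, scored by the
#' arithmetic mean of their edge weights, capped at `max_paths` per pair
#' by descending score (ties broken lexicographically by the node-id
#' sequence).
#'
#' @param graph A `knowledge_graph`.
#' @param selected Character vector of >= 2 entity ids.
#' @param max_len Maximum path length in edges.
#' @param max_paths Cap per pair.
#' @return List of `evidence_path` objects: `nodes` (id sequence),
#'   `edges` (data.frame of the traversed collapsed edges), `score`,
#'   `pair` (sorted endpoint ids).
#' @export
enumerate_paths <- function(graph, selected, max_len = 4L,
                            max_paths = 25L) {
  stopifnot(inherits(graph, "knowledge_graph"))
  selected <- unique(as.character(selected))
  if (length(selected) < 2L)
    stop("need at least 2 selected nodes", call. = FALSE)
  missing <- setdiff(selected, graph$nodes$entity_id)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  edge_lookup <- .collapsed_edge_table(graph)
  out <- list()
  pairs <- utils::combn(sort(selected), 2L, simplify = FALSE)
  for (pr in pairs) {
    vp <- igraph::all_simple_paths(ig, from = pr[1], to = pr[2],
                                   cutoff = max_len)
    if (length(vp) == 0L) next
    paths <- lapply(vp, function(v) {
      ids <- igraph::as_ids(v)
      ed <- .path_edges(edge_lookup, ids)
      structure(list(nodes = ids, edges = ed, score = mean(ed$weight),
                     pair = pr), class = "evidence_path")
    })
    sc <- vapply(paths, function(p) p$score, numeric(1))
    keyseq <- vapply(paths, function(p) paste(p$nodes, collapse = "\r"),
                     character(1))
    ord <- order(-sc, keyseq)
    paths <- paths[ord][seq_len(min(length(paths), max_paths))]
    out <- c(out, paths)
  }
  out
}

# Collapsed (max-weight per unordered pair) edge table keyed by pair.
.collapsed_edge_table <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(e)
  pair <- ifelse(e$source < e$target,
                 paste(e$source, e$target, sep = "\r"),
                 paste(e$target, e$source, sep = "\r"))
  ord <- order(pair, -e$weight, e$source, e$target, e$label)
  e <- e[ord, , drop = FALSE]
  e <- e[!duplicated(pair[ord]), , drop = FALSE]
  e$pair_key <- ifelse(e$source < e$target,
                       paste(e$source, e$target, sep = "\r"),
                       paste(e$target, e$source, sep = "\r"))
  e
}

.path_edges <- function(edge_lookup, ids) {
  keys <- vapply(seq_len(length(ids) - 1L), function(k) {
    a <- ids[k]; b <- ids[k + 1L]
    if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  }, character(1))
  rows <- match(keys, edge_lookup$pair_key)
  stopifnot(!anyNA(rows))
  edge_lookup[rows, , drop = FALSE]
}

#' Score of an evidence path
#'
#' The arithmetic mean of the path's edge weights
#' (`(tfidf * bio) / ambiguity` each).
#'
#' @param path An `evidence_path`, or a numeric vector of edge weights.
#' @return Mean edge weight.
#' @export
score_path <- function(path) {
  w <- if (inherits(path, "evidence_path")) path$edges$weight
       else as.numeric(path)
  if (length(w) == 0L) stop("empty path", call. = FALSE)
  mean(w)
}

#' Select a coverage-maximizing subset of paths
#'
#' Greedy selection: repeatedly take the highest-scoring path that covers
#' a not-yet-covered endpoint pair until every reachable pair is covered,
#' then fill the remaining budget by descending score. Ties are broken
#' lexicographically by node-id sequence, so the result is independent of
#' input order.
#'
#' @param paths List of `evidence_path` (from [enumerate_paths()]).
#' @param budget Maximum number of paths to keep (>= 1).
#' @return Sublist of `paths`.
#' @export
select_paths <- function(paths, budget = 10L) {
  stopifnot(budget >= 1L)
  if (length(paths) == 0L) return(list())
  sc <- vapply(paths, function(p) p$score, numeric(1))
  keyseq <- vapply(paths, function(p) paste(p$nodes, collapse = "\r"),
                   character(1))
  ord <- order(-sc, keyseq)
  paths <- paths[ord]
  pairs <- vapply(paths, function(p) paste(p$pair, collapse = "\r"),
                  character(1))
  chosen <- integer()
  covered <- character()
  # coverage pass
  for (i in seq_along(paths)) {
    if (length(chosen) >= budget) break
    if (!pairs[i] %in% covered) {
      chosen <- c(chosen, i)
      covered <- c(covered, pairs[i])
    }
  }
  # fill pass
  for (i in seq_along(paths)) {
    if (length(chosen) >= budget) break
    if (!i %in% chosen) chosen <- c(chosen, i)
  }
  paths[sort(chosen)]
}

#' Build a citation-bearing prompt payload
#'
#' Collects the deduplicated provenance sentences of the selected paths'
#' edges, each tagged with a citation key `doc_id:sentence_index`, and
#' wraps them in an instruction asking for a summary of the
#' relationships among the query entities restricted to that evidence.
#' Generation temperature is recorded as 0.
#'
#' @param selected_paths List of `evidence_path`.
#' @param corpus Optional `litkg_corpus`; when given, citation keys are
#'   checked to resolve against it.
#' @param query_entities Character vector of entity names to summarize.
#' @param temperature Generation temperature recorded in the payload.
#' @return A `prompt_payload`: `instruction`, `evidence` (data.frame
#'   `doc_id`, `sentence_index`, `sentence_text`, `citation`),
#'   `entities`, `temperature`.
#' @export
build_prompt <- function(selected_paths, corpus = NULL, query_entities,
                         temperature = 0) {
  ev <- empty_provenance()
  for (p in selected_paths) {
    for (k in seq_len(nrow(p$edges))) {
      ev <- rbind(ev, p$edges$provenance[[k]])
    }
  }
  ev <- unique(ev[, c("doc_id", "sentence_index", "sentence_text")])
  ev <- ev[order(ev$doc_id, ev$sentence_index), , drop = FALSE]
  rownames(ev) <- NULL
  if (!is.null(corpus) && nrow(ev) > 0L) {
    bad <- !ev$doc_id %in% names(corpus$documents)
    if (any(bad))
      stop("citation doc_id not in corpus: ",
           paste(unique(ev$doc_id[bad]), collapse = ", "), call. = FALSE)
  }
  ev$citation <- sprintf("[%s:%d]", ev$doc_id, ev$sentence_index)
  instruction <- if (nrow(ev) == 0L) {
    paste0("NO EVIDENCE AVAILABLE: no graph paths connect the selected ",
           "entities (", paste(query_entities, collapse = ", "),
           "). Do not generate a summary.")
  } else {
    paste0("Summarize the biomedical relationships among the entities ",
           paste(query_entities, collapse = ", "),
           ", using ONLY the evidence sentences below. Cite each claim ",
           "with the bracketed key of its supporting sentence.")
  }
  structure(list(instruction = instruction, evidence = ev,
                 entities = query_entities,
                 temperature = temperature),
            class = "prompt_payload")
}

#' @export
print.prompt_payload <- function(x, ...) {
  cat("<prompt_payload> entities:", paste(x$entities, collapse = ", "),
      sprintf("| %d evidence sentence(s) | temperature %g\n",
              nrow(x$evidence), x$temperature))
  invisible(x)
}

#' Render a prompt payload as plain text
#'
#' The text a hosted LLM client would receive: instruction followed by
#' the cited evidence sentences.
#'
#' @param payload A `prompt_payload`.
#' @return A single string.
#' @export
render_prompt <- function(payload) {
  stopifnot(inherits(payload, "prompt_payload"))
  lines <- payload$instruction
  if (nrow(payload$evidence) > 0L) {
    lines <- c(lines, "", paste0("- ", payload$evidence$sentence_text, " ",
                                 payload$evidence$citation))
  }
  paste(lines, collapse = "\n")
}

#' LLM client interface
#'
#' A client is a function `f(payload)` returning text. The bundled no-op
#' client returns the rendered payload verbatim, keeping the pipeline
#' fully offline; a hosted client (e.g. an OpenAI adapter at temperature
#' 0) can be supplied with the same signature.
#'
#' @return A client function.
#' @export
noop_llm_client <- function() {
  function(payload) render_prompt(payload)
}

#' Run graph retrieval for a set of selected entities
#'
#' Convenience wrapper: [enumerate_paths()], [select_paths()],
#' [build_prompt()], then the client.
#'
#' @param graph A `knowledge_graph`.
#' @param selected Character vector of >= 2 entity ids.
#' @param corpus Optional corpus for citation checking.
#' @param max_len,max_paths,budget Retrieval bounds (see
#'   [enumerate_paths()] and [select_paths()]).
#' @param client An LLM client function; default [noop_llm_client()].
#' @return list with `paths`, `payload`, `summary` (the client output).
#' @export
graph_rag <- function(graph, selected, corpus = NULL, max_len = 4L,
                      max_paths = 25L, budget = 10L,
                      client = noop_llm_client()) {
  paths <- enumerate_paths(graph, selected, max_len = max_len,
                           max_paths = max_paths)
  sel <- select_paths(paths, budget = budget)
  names <- graph$nodes$name[match(selected, graph$nodes$entity_id)]
  payload <- build_prompt(sel, corpus = corpus,
                          query_entities = ifelse(is.na(names), selected,
                                                  names))
  list(paths = sel, payload = payload, summary = client(payload))
}
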