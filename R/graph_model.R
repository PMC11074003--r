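# The biomedical knowledge graph: a directed labeled multigraph of
# entities and scored verbal relations, with provenance down to the
# supporting sentence. Analytics (paths, components, traversals,
# betweenness, communities) run on an undirected view that collapses
# parallel edges to the max-weight edge per node pair; shortest-path
# lengths are 1/weight so that strong edges are short.

#' Construct a knowledge graph
#'
#' Low-level constructor with validation; most users get graphs from
#' [assemble_graph()] or [build_knowledge_graph()].
#'
#' @param nodes data.frame with columns `entity_id`, `name`, `category`,
#'   `pagerank`.
#' @param edges data.frame with columns `source`, `target`, `label`,
#'   `tfidf`, `bio`, `ambiguity`, `weight`, `support_count`, `df`, plus
#'   list columns `actions` and `provenance`.
#' @param n_docs Number of documents the graph was built from.
#' @return A `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges, n_docs) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("entity_id", "name", "category", "pagerank")
  need_e <- c("source", "target", "label", "tfidf", "bio", "ambiguity",
              "weight", "support_count", "df", "actions", "provenance")
  if (!all(need_n %in% names(nodes)))
    stop("nodes missing columns: ",
         paste(setdiff(need_n, names(nodes)), collapse = ", "), call. = FALSE)
  if (!all(need_e %in% names(edges)))
    stop("edges missing columns: ",
         paste(setdiff(need_e, names(edges)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(nodes$entity_id))
    stop("duplicate node entity_id", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges$source == edges$target))
      stop("self-loop edge (source == target)", call. = FALSE)
    missing <- setdiff(c(edges$source, edges$target), nodes$entity_id)
    if (length(missing))
      stop("edge endpoints not in nodes: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, n_docs = as.integer(n_docs)),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d edges, built from %d document(s)\n",
              nrow(x$nodes), nrow(x$edges), x$n_docs))
  if (nrow(x$edges) > 0L) {
    top <- x$edges[order(-x$edges$weight), , drop = FALSE]
    top <- utils::head(top, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s -[%s]-> %s  (w=%.3f)\n", top$source[i],
                  top$label[i], top$target[i], top$weight[i]))
  }
  invisible(x)
}

empty_kg_nodes <- function() {
  data.frame(entity_id = character(), name = character(),
             category = character(), pagerank = numeric(),
             stringsAsFactors = FALSE)
}

empty_kg_edges <- function() {
  df <- data.frame(source = character(), target = character(),
                   label = character(), tfidf = numeric(), bio = numeric(),
                   ambiguity = integer(), weight = numeric(),
                   support_count = integer(), df = integer(),
                   stringsAsFactors = FALSE)
  df$actions <- list()
  df$provenance <- list()
  df
}

#' Assemble a knowledge graph from candidate edges
#'
#' Candidates with identical `(source, target, label)` merge into one
#' edge, aggregating sentence provenance and per-document support counts.
#' Edge scores are then computed: raw TF-IDF min-max normalized across
#' the graph's edges, bio from the actions against the verb lexicon,
#' ambiguity = action count, weight = (tfidf * bio) / ambiguity. Node
#' PageRank is the uniform-teleport personalized PageRank; re-rank for a
#' query with [personalized_pagerank()].
#'
#' @param candidates Candidate-edge data.frame from [extract_relations()].
#' @param corpus The source `litkg_corpus` (fixes `n_docs`).
#' @param verbs A [verb_lexicon()] for bio scoring.
#' @param lexicon Optional `entity_lexicon` supplying canonical node
#'   names; otherwise the first-seen mention surface is used.
#' @param mentions Optional mention data.frame; with
#'   `include_isolated = TRUE`, linked entities without edges become
#'   isolated nodes.
#' @param include_isolated Keep linked but unconnected entities as nodes.
#' @return A `knowledge_graph`.
#' @export
assemble_graph <- function(candidates, corpus, verbs, lexicon = NULL,
                           mentions = NULL, include_isolated = FALSE) {
  stopifnot(inherits(corpus, "litkg_corpus"))
  n_docs <- corpus$n_docs
  if (nrow(candidates) == 0L && !(include_isolated && !is.null(mentions))) {
    return(knowledge_graph(empty_kg_nodes(), empty_kg_edges(), n_docs))
  }
  edges <- empty_kg_edges()
  if (nrow(candidates) > 0L) {
    key <- paste(candidates$source_id, candidates$target_id,
                 candidates$label, sep = "\r")
    groups <- split(seq_len(nrow(candidates)), key)
    groups <- groups[order(vapply(groups, min, integer(1)))]
    rows <- lapply(groups, function(idx) {
      g <- candidates[idx, , drop = FALSE]
      prov <- data.frame(doc_id = g$doc_id,
                         sentence_index = g$sentence_index,
                         sentence_text = g$sentence_text,
                         stringsAsFactors = FALSE)
      prov <- unique(prov)
      acts <- g$actions[[1]]
      row <- data.frame(source = g$source_id[1], target = g$target_id[1],
                        label = g$label[1], tfidf = NA_real_,
                        bio = bio_score(acts, verbs),
                        ambiguity = ambiguity(acts),
                        weight = NA_real_,
                        support_count = nrow(prov),
                        df = length(unique(prov$doc_id)),
                        stringsAsFactors = FALSE)
      row$actions <- list(acts)
      row$provenance <- list(prov)
      row
    })
    edges <- do.call(rbind, rows)
    rownames(edges) <- NULL
    raw <- tfidf_raw(edges$support_count, edges$df, n_docs)
    edges$tfidf <- minmax_normalize(raw, raw)
    edges$weight <- edge_weight(edges$tfidf, edges$bio, edges$ambiguity)
  }
  # node table
  ids <- unique(c(edges$source, edges$target))
  info <- list()
  if (nrow(candidates) > 0L) {
    for (side in c("source", "target")) {
      info[[side]] <- data.frame(
        entity_id = candidates[[paste0(side, "_id")]],
        name = candidates[[paste0(side, "_surface")]],
        category = candidates[[paste0(side, "_category")]],
        stringsAsFactors = FALSE)
    }
  }
  if (include_isolated && !is.null(mentions) && nrow(mentions) > 0L) {
    info$mentions <- data.frame(entity_id = mentions$entity_id,
                                name = mentions$surface,
                                category = mentions$category,
                                stringsAsFactors = FALSE)
    ids <- unique(c(ids, mentions$entity_id))
  }
  info <- do.call(rbind, info)
  info <- info[!duplicated(info$entity_id), , drop = FALSE]
  nodes <- data.frame(entity_id = ids, stringsAsFactors = FALSE)
  nodes$name <- info$name[match(ids, info$entity_id)]
  nodes$category <- info$category[match(ids, info$entity_id)]
  if (!is.null(lexicon)) {
    hit <- match(ids, lexicon$entity_id)
    nodes$name <- ifelse(is.na(hit), nodes$name, lexicon$name[hit])
    nodes$category <- ifelse(is.na(hit), nodes$category,
                             lexicon$category[hit])
  }
  nodes$pagerank <- NA_real_
  g <- knowledge_graph(nodes, edges, n_docs)
  if (nrow(nodes) > 0L) {
    g$nodes$pagerank <- unname(personalized_pagerank(g)[nodes$entity_id])
  }
  g
}

#' Undirected or directed igraph view of a knowledge graph
#'
#' `collapse = "max"` keeps, per unordered node pair, the parallel edge
#' of maximum weight (ties: first by source/target/label order) — the
#' view used by analytics. `collapse = "none"` keeps the full multigraph.
#'
#' @param graph A `knowledge_graph`.
#' @param collapse `"max"` or `"none"`.
#' @param directed Build a directed graph.
#' @return An igraph object with a `weight` edge attribute.
#' @export
kg_igraph <- function(graph, collapse = c("max", "none"),
                      directed = FALSE) {
  collapse <- match.arg(collapse)
  e <- graph$edges
  if (collapse == "max" && nrow(e) > 1L) {
    pair <- ifelse(e$source < e$target,
                   paste(e$source, e$target, sep = "\r"),
                   paste(e$target, e$source, sep = "\r"))
    ord <- order(pair, -e$weight, e$source, e$target, e$label)
    e <- e[ord, , drop = FALSE]
    e <- e[!duplicated(pair[ord]), , drop = FALSE]
  }
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target, weight = e$weight,
                   label = e$label, tfidf = e$tfidf, bio = e$bio,
                   ambiguity = e$ambiguity, support_count = e$support_count,
                   df = e$df,
                   actions = vapply(e$actions, paste, character(1),
                                    collapse = "; "),
                   stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = graph$nodes$entity_id,
                          entity_name = graph$nodes$name,
                          category = graph$nodes$category,
                          pagerank = graph$nodes$pagerank,
                          stringsAsFactors = FALSE))
  ig <- igraph::set_graph_attr(ig, "n_docs", graph$n_docs)
  ig
}

# Distances for shortest-path style analytics: 1/weight, with
# zero-weight edges excluded (infinite length).
.kg_distances_graph <- function(graph) {
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  w <- igraph::E(ig)$weight
  ig <- igraph::delete_edges(ig, igraph::E(ig)[w <= 0])
  igraph::E(ig)$dist <- 1 / igraph::E(ig)$weight
  ig
}

#' Shortest path between two entities
#'
#' Undirected view; edge length is `1/weight` (strong edges are short);
#' zero-weight edges are excluded.
#'
#' @param graph A `knowledge_graph`.
#' @param from,to Entity ids.
#' @return list with `nodes` (entity-id sequence, empty when no path
#'   exists) and `length` (sum of 1/weight, `Inf` when no path).
#' @export
kg_shortest_path <- function(graph, from, to) {
  stopifnot(all(c(from, to) %in% graph$nodes$entity_id))
  ig <- .kg_distances_graph(graph)
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = from, to = to,
                           weights = igraph::E(ig)$dist, output = "vpath"))
  nodes <- igraph::as_ids(sp$vpath[[1]])
  len <- suppressWarnings(
    igraph::distances(ig, v = from, to = to,
                      weights = igraph::E(ig)$dist)[1, 1])
  list(nodes = nodes, length = len)
}

#' Connected components of the undirected view
#' @param graph A `knowledge_graph`.
#' @return Named integer vector: component id per entity id.
#' @export
kg_components <- function(graph) {
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  igraph::components(ig)$membership
}

#' Breadth-first / depth-first traversal orders
#' @param graph A `knowledge_graph`.
#' @param start Entity id to start from.
#' @return Character vector of entity ids in visit order (the start's
#'   component only).
#' @export
kg_bfs <- function(graph, start) {
  stopifnot(start %in% graph$nodes$entity_id)
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  ord <- igraph::bfs(ig, root = start, unreachable = FALSE)$order
  ids <- igraph::as_ids(ord)
  ids[!is.na(ids)]
}

#' @rdname kg_bfs
#' @export
kg_dfs <- function(graph, start) {
  stopifnot(start %in% graph$nodes$entity_id)
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  ord <- igraph::dfs(ig, root = start, unreachable = FALSE)$order
  ids <- igraph::as_ids(ord)
  ids[!is.na(ids)]
}

#' Normalized betweenness centrality
#'
#' Undirected collapsed view with `1/weight` distances.
#'
#' @param graph A `knowledge_graph`.
#' @return Named numeric vector per entity id.
#' @export
kg_betweenness <- function(graph) {
  ig <- .kg_distances_graph(graph)
  b <- igraph::betweenness(ig, weights = igraph::E(ig)$dist,
                           normalized = TRUE)
  full <- setNames(numeric(nrow(graph$nodes)), graph$nodes$entity_id)
  full[names(b)] <- b
  full
}

#' Community detection (greedy modularity)
#'
#' Greedy modularity optimization on the undirected collapsed view with
#' edge weights as affinities. Deterministic.
#'
#' @param graph A `knowledge_graph`.
#' @return Named integer vector: community id per entity id.
#' @export
kg_communities <- function(graph) {
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  w <- igraph::E(ig)$weight
  w[w <= 0] <- .Machine$double.eps
  cl <- igraph::cluster_fast_greedy(ig, weights = w)
  igraph::membership(cl)
}

#' Neighborhood of a node
#'
#' @param graph A `knowledge_graph`.
#' @param node Entity id.
#' @param radius Hop radius (>= 1).
#' @return Character vector of entity ids within `radius` hops
#'   (including `node`).
#' @export
kg_neighborhood <- function(graph, node, radius = 1L) {
  stopifnot(node %in% graph$nodes$entity_id, radius >= 1L)
  ig <- kg_igraph(graph, collapse = "max", directed = FALSE)
  igraph::as_ids(igraph::ego(ig, order = radius, nodes = node)[[1]])
}

#' Gene-disease association recall
#'
#' The fraction of gold (gene, disease) pairs connected by at least one
#' edge in either direction.
#'
#' @param graph A `knowledge_graph`.
#' @param gold_pairs data.frame with columns `gene_id`, `disease_id`
#'   (entity ids in the graph's id space).
#' @return Recall in `[0, 1]`.
#' @export
gda_recall <- function(graph, gold_pairs) {
  stopifnot(is.data.frame(gold_pairs),
            all(c("gene_id", "disease_id") %in% names(gold_pairs)))
  if (nrow(gold_pairs) == 0L) stop("empty gold set", call. = FALSE)
  e <- graph$edges
  have <- unique(c(paste(e$source, e$target, sep = "\r"),
                   paste(e$target, e$source, sep = "\r")))
  hit <- paste(gold_pairs$gene_id, gold_pairs$disease_id, sep = "\r") %in% have
  mean(hit)
}
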