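# Edge and node scoring.
#
# Each edge carries three values: TF-IDF (relevance of the relation
# across the corpus of n_docs documents), bio (similarity of its actions
# to a curated list of biological verb forms, via normalized edit
# distance), and ambiguity (the number of actions composing the label,
# which penalizes possibly spurious multi-action edges). The combined
# edge weight is (tfidf * bio) / ambiguity. Nodes are ranked by
# personalized PageRank with the query entities as teleport nodes.

#' Raw TF-IDF score of one edge
#'
#' Log-scaled term frequency with add-one-smoothed inverse document
#' frequency: `(1 + ln(tf)) * (ln((1 + n_docs) / (1 + df)) + 1)`. `tf`
#' counts supporting sentences across the corpus; `df` counts documents
#' with at least one support. Smoothing keeps single-document corpora
#' (a common use case: one uploaded paper) away from all-zero weights.
#'
#' @param tf_total Total supporting-sentence count (>= 1).
#' @param df Number of documents with >= 1 support (1 <= df <= n_docs).
#' @param n_docs Corpus size.
#' @return Non-negative raw score (normalized per graph by
#'   [compute_tfidf()]).
#' @export
tfidf_raw <- function(tf_total, df, n_docs) {
  stopifnot(all(tf_total >= 1), all(df >= 1), all(df <= n_docs),
            n_docs >= 1)
  (1 + log(tf_total)) * (log((1 + n_docs) / (1 + df)) + 1)
}

#' Normalized TF-IDF of one edge within a graph
#'
#' Min-max normalizes the edge's raw score over the raw scores of all
#' edges in the graph, to `[0, 1]`. A single-edge graph (or an all-equal
#' raw vector) scores 1.
#'
#' @param tf_by_doc Named numeric vector: supporting-sentence count per
#'   document for this edge.
#' @param n_docs Corpus size.
#' @param all_raw Numeric vector of raw scores ([tfidf_raw()]) of all
#'   edges in the graph (including this one).
#' @return Normalized TF-IDF in `[0, 1]`.
#' @export
compute_tfidf <- function(tf_by_doc, n_docs, all_raw) {
  if (length(tf_by_doc) == 0L || sum(tf_by_doc) < 1)
    stop("edge has zero support", call. = FALSE)
  raw <- tfidf_raw(sum(tf_by_doc), sum(tf_by_doc > 0), n_docs)
  minmax_normalize(raw, all_raw)
}

minmax_normalize <- function(x, all_values) {
  lo <- min(all_values); hi <- max(all_values)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) return(rep(1, length(x)))
  (x - lo) / (hi - lo)
}

#' Normalized Levenshtein edit distance
#'
#' `Levenshtein(a, b) / max(nchar(a), nchar(b))`, in `[0, 1]`; symmetric;
#' 0 iff the strings are equal (two empty strings give 0 by convention).
#'
#' @param a,b Strings (vectorized, recycled).
#' @return Numeric vector of normalized distances.
#' @export
normalized_edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- mapply(function(x, y) {
    mx <- max(nchar(x), nchar(y))
    if (mx == 0L) return(0)
    utils::adist(x, y)[1, 1] / mx
  }, a, b, USE.NAMES = FALSE)
  as.numeric(d)
}

#' Bio score of an edge's actions
#'
#' For each action, similarity = 1 - min over the verb lexicon of the
#' normalized edit distance (case-folded); the edge's bio score is the
#' mean similarity over its actions. A label made of curated biological
#' verb forms scores 1; an arbitrary token scores near 0.
#'
#' @param actions Character vector of action surfaces (non-empty).
#' @param verbs A [verb_lexicon()] (non-empty).
#' @return Bio score in `[0, 1]`.
#' @export
bio_score <- function(actions, verbs) {
  if (length(actions) == 0L) stop("no actions", call. = FALSE)
  v <- tolower(as.character(verbs))
  if (length(v) == 0L)
    stop("bio scoring requires a non-empty verb lexicon", call. = FALSE)
  sims <- vapply(tolower(actions), function(a) {
    1 - min(normalized_edit_distance(a, v))
  }, numeric(1), USE.NAMES = FALSE)
  mean(sims)
}

#' Ambiguity of an edge
#'
#' The number of actions composing the edge label. Many actions between a
#' pair often signal unannotated intervening mentions, so ambiguity
#' divides the edge weight.
#'
#' @param edge A one-row candidate-edge data.frame, a list with an
#'   `actions` field, or a character vector of actions.
#' @return Integer count >= 1.
#' @export
ambiguity <- function(edge) {
  acts <- if (is.character(edge)) edge
          else if (is.data.frame(edge)) edge$actions[[1]]
          else edge$actions
  n <- length(acts)
  if (n < 1L) stop("edge has no actions", call. = FALSE)
  as.integer(n)
}

#' Combined edge weight
#'
#' `(tfidf * bio) / ambiguity`.
#'
#' @param tfidf,bio Scores in `[0, 1]`.
#' @param ambiguity Integer >= 1.
#' @return Edge weight (vectorized).
#' @export
edge_weight <- function(tfidf, bio, ambiguity) {
  stopifnot(all(tfidf >= 0 & tfidf <= 1), all(bio >= 0 & bio <= 1))
  if (any(ambiguity < 1)) stop("ambiguity must be >= 1", call. = FALSE)
  (tfidf * bio) / ambiguity
}

#' Personalized PageRank over a knowledge graph
#'
#' Power iteration on the edge-weight-proportional transition structure
#' of the directed graph. The teleport distribution is uniform over
#' `teleport_nodes` (uniform over all nodes when empty); the mass of
#' dangling nodes (no out-edges) is redistributed to the teleport
#' vector. Nodes whose out-edges all have zero weight transition
#' uniformly over their out-neighbours.
#'
#' @param graph A `knowledge_graph`.
#' @param teleport_nodes Character vector of entity ids (subset of the
#'   graph's nodes); the query nodes.
#' @param damping Damping factor in `[0, 1)` (config `scoring.damping`).
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum power iterations.
#' @return Named numeric vector of scores, one per node, summing to 1.
#' @export
personalized_pagerank <- function(graph, teleport_nodes = character(),
                                  damping = 0.85, tol = 1e-9,
                                  max_iter = 200L) {
  stopifnot(inherits(graph, "knowledge_graph"))
  ids <- graph$nodes$entity_id
  n <- length(ids)
  if (n == 0L) stop("empty graph", call. = FALSE)
  if (length(teleport_nodes)) {
    missing <- setdiff(teleport_nodes, ids)
    if (length(missing))
      stop("teleport nodes not in graph: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  v <- numeric(n)
  if (length(teleport_nodes)) {
    v[match(unique(teleport_nodes), ids)] <- 1 / length(unique(teleport_nodes))
  } else {
    v[] <- 1 / n
  }
  e <- graph$edges
  if (nrow(e) > 0L) {
    si <- match(e$source, ids); ti <- match(e$target, ids)
    w <- e$weight
    # per-source normalization; zero-weight out-profiles become uniform
    out_w <- tapply(w, si, sum)
    zero_src <- as.integer(names(out_w))[out_w <= 0]
    w[si %in% zero_src] <- 1
    out_w <- tapply(w, si, sum)
    p_edge <- w / out_w[as.character(si)]
  } else {
    si <- ti <- integer(); p_edge <- numeric()
  }
  has_out <- logical(n)
  has_out[unique(si)] <- TRUE
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    flow <- numeric(n)
    if (length(si)) {
      agg <- rowsum(p[si] * p_edge, group = ti)
      flow[as.integer(rownames(agg))] <- agg[, 1]
    }
    dangling_mass <- sum(p[!has_out])
    p_new <- damping * (flow + dangling_mass * v) + (1 - damping) * v
    residual <- sum(abs(p_new - p))
    p <- p_new
    if (residual < tol) {
      names(p) <- ids
      return(p / sum(p))
    }
  }
  stop(sprintf("personalized PageRank did not converge after %d iterations (L1 residual %.3e)",
               max_iter, residual), call. = FALSE)
}
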