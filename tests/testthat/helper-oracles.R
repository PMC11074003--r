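# Independent oracles and fixture builders. These deliberately reimplement
# the quantities they check (dense matrices, plain dynamic programming,
# recursive enumeration) so they share no code with the package internals.

# --- Levenshtein distance: classic O(nm) dynamic program ------------------
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  if (n > 0 && m > 0) {
    for (i in 1:n) {
      for (j in 1:m) {
        cost <- if (ca[i] == cb[j]) 0L else 1L
        d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                               d[i, j] + cost)
      }
    }
  }
  d[n + 1, m + 1]
}

dp_normalized_levenshtein <- function(a, b) {
  mx <- max(nchar(a), nchar(b))
  if (mx == 0) return(0)
  dp_levenshtein(a, b) / mx
}

# --- Personalized PageRank: dense-matrix power iteration ------------------
# Same model as the package claims (weight-proportional transitions,
# uniform rows for zero-weight out-profiles, dangling mass to the teleport
# vector) but built as an explicit n x n matrix.
dense_ppr_oracle <- function(g, teleport = character(), damping = 0.85,
                             iters = 5000, tol = 1e-14) {
  ids <- g$nodes$entity_id
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(g$edges))) {
    P[g$edges$source[k], g$edges$target[k]] <-
      P[g$edges$source[k], g$edges$target[k]] + g$edges$weight[k]
  }
  has_out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    out_edges <- g$edges$source == ids[i]
    if (any(out_edges)) {
      has_out[i] <- TRUE
      if (sum(P[i, ]) <= 0) {
        nb <- unique(g$edges$target[out_edges])
        P[i, nb] <- 1
      }
      P[i, ] <- P[i, ] / sum(P[i, ])
    }
  }
  v <- rep(0, n); names(v) <- ids
  if (length(teleport)) v[unique(teleport)] <- 1 / length(unique(teleport))
  else v[] <- 1 / n
  p <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    p_new <- damping * (as.vector(t(P) %*% p) + sum(p[!has_out]) * v) +
      (1 - damping) * v
    if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  names(p) <- ids
  p / sum(p)
}

# --- All simple paths between two nodes (recursive enumeration) -----------
# adjacency from an undirected edge list; returns list of node-id vectors
enumerate_simple_paths_oracle <- function(edge_df, from, to, max_len) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (k in seq_len(nrow(edge_df))) {
    add(edge_df$source[k], edge_df$target[k])
    add(edge_df$target[k], edge_df$source[k])
  }
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == to && length(path) > 1L) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    if (length(path) - 1L >= max_len) return()
    for (nb in adj[[cur]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(from)
  out
}

# --- Random knowledge graphs ----------------------------------------------
# Valid knowledge_graph objects with arbitrary consistent scores.
make_random_kg <- function(n_nodes, edge_prob = 0.4, seed = 1,
                           n_docs = 3L) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  nodes <- data.frame(entity_id = ids, name = tolower(ids),
                      category = "gene", pagerank = NA_real_,
                      stringsAsFactors = FALSE)
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  e <- empty_kg_edges_test()
  if (nrow(pairs) > 0) {
    tf <- runif(nrow(pairs))
    bio <- runif(nrow(pairs))
    e <- data.frame(source = pairs$s, target = pairs$t,
                    label = paste0("acts_", seq_len(nrow(pairs))),
                    tfidf = tf, bio = bio, ambiguity = 1L,
                    weight = tf * bio, support_count = 1L, df = 1L,
                    stringsAsFactors = FALSE)
    e$actions <- as.list(paste0("acts_", seq_len(nrow(pairs))))
    e$provenance <- lapply(seq_len(nrow(pairs)), function(k) {
      data.frame(doc_id = "docA", sentence_index = k - 1L,
                 sentence_text = paste("sentence", k),
                 stringsAsFactors = FALSE)
    })
  }
  knowledge_graph(nodes, e, n_docs = n_docs)
}

empty_kg_edges_test <- function() {
  df <- data.frame(source = character(), target = character(),
                   label = character(), tfidf = numeric(), bio = numeric(),
                   ambiguity = integer(), weight = numeric(),
                   support_count = integer(), df = integer(),
                   stringsAsFactors = FALSE)
  df$actions <- list()
  df$provenance <- list()
  df
}

# --- Worked-example setups -------------------------------------------------
fig1a_setup <- function() {
  list(
    lexicon = entity_lexicon(entity_id = c("G1", "D1"),
                             name = c("TP53 expression", "colon cancer"),
                             category = c("gene", "disease")),
    verbs = verb_lexicon(c("increase", "inhibit")),
    doc = document("f1a", "TP53 expression increased in colon cancer.")
  )
}

fig1b_setup <- function() {
  list(
    lexicon = entity_lexicon(entity_id = c("G4", "D1"),
                             name = c("circPIP5K1A", "colon cancer"),
                             category = c("gene", "disease")),
    verbs = verb_lexicon(c("attenuate", "reduce", "facilitate",
                           "increase")),
    doc = document("f1b", paste(
      "circPIP5K1A overexpression attenuates cell viability,",
      "reduces cell motility, and facilitates colon cancer progression."))
  )
}

# --- Synthetic study conditions -------------------------------------------
# The planted gene/disease/process triples used by end-to-end tests.
study_triples <- function() {
  data.frame(
    source_id = c("G1", "G2", "G3", "G4", "C1", "G1", "G2", "G3", "C2", "C3"),
    verb_form = c("increase", "inhibit", "promote", "attenuate", "block",
                  "induce", "suppress", "regulate", "reduce", "bind"),
    target_id = c("D1", "D2", "D3", "D1", "D2", "P1", "P2", "D2", "D3", "D1"),
    n_occurrences = 2L,
    stringsAsFactors = FALSE)
}

study_spec <- function(seed = 1, n_docs = 20, distractor_rate = 0,
                       multi_verb_rate = 0) {
  synthetic_spec(seed = seed, n_docs = n_docs,
                 entities = example_lexicon(), verbs = example_verbs(),
                 planted_triples = study_triples(),
                 distractor_rate = distractor_rate,
                 multi_verb_rate = multi_verb_rate)
}
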