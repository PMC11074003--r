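# Graph assembly, analytics toolkit, and the GDA-recall harness.

two_doc_candidates <- function() {
  mk <- function(doc, sent, label, acts = label) {
    row <- data.frame(source_id = "G1", target_id = "D1",
                      source_surface = "TP53", target_surface = "colon cancer",
                      source_category = "gene", target_category = "disease",
                      label = label, doc_id = doc, sentence_index = sent,
                      sentence_text = paste("TP53", label, "colon cancer"),
                      stringsAsFactors = FALSE)
    row$actions <- list(acts)
    row
  }
  rbind(mk("d1", 0L, "increases"), mk("d2", 0L, "increases"))
}

toy_corpus <- function(n) {
  corpus(lapply(seq_len(n), function(i)
    document(paste0("d", i), "placeholder text.")))
}

test_that("assemble_graph merges identical triples and keeps parallel labels", {
  verbs <- example_verbs()
  g <- assemble_graph(two_doc_candidates(), toy_corpus(2), verbs)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$df, 2L)
  expect_equal(g$edges$support_count, 2L)
  expect_equal(nrow(g$edges$provenance[[1]]), 2L)
  expect_equal(g$edges$ambiguity, 1L)
  expect_equal(g$edges$weight,
               edge_weight(g$edges$tfidf, g$edges$bio, g$edges$ambiguity))
  expect_false(anyNA(g$nodes$pagerank))

  # two labels between the same pair: two parallel edges
  cand <- rbind(two_doc_candidates()[1, ], two_doc_candidates()[1, ])
  cand$label[2] <- "suppresses"
  cand$actions[[2]] <- "suppresses"
  g2 <- assemble_graph(cand, toy_corpus(2), verbs)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(nrow(g2$nodes), 2L)

  # empty candidates: empty graph
  g0 <- assemble_graph(litkg:::empty_candidates(), toy_corpus(1), verbs)
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("edge count and support totals reconcile with candidates", {
  gen <- generate_corpus(study_spec(seed = 9, n_docs = 10,
                                    multi_verb_rate = 0.25))
  gaz <- build_gazetteer(example_lexicon())
  cands <- do.call(rbind, lapply(gen$corpus$documents, function(doc) {
    extract_relations(doc, annotate(doc, gaz), example_verbs())
  }))
  g <- assemble_graph(cands, gen$corpus, example_verbs())
  expect_lte(nrow(g$edges), nrow(cands))
  expect_equal(sum(g$edges$support_count), nrow(unique(
    cands[c("source_id", "target_id", "label", "doc_id",
            "sentence_index")])))
  for (i in seq_len(nrow(g$edges))) {
    expect_equal(g$edges$support_count[i], nrow(g$edges$provenance[[i]]))
    expect_equal(g$edges$df[i],
                 length(unique(g$edges$provenance[[i]]$doc_id)))
    expect_lte(g$edges$df[i], g$n_docs)
  }
  # tfidf normalized to [0,1] with at least one edge at 1
  expect_true(all(g$edges$tfidf >= 0 & g$edges$tfidf <= 1))
  expect_equal(max(g$edges$tfidf), 1)
})

test_that("lexicon supplies canonical node names and isolated nodes opt in", {
  verbs <- example_verbs()
  cand <- two_doc_candidates()
  lex <- example_lexicon()
  g <- assemble_graph(cand, toy_corpus(2), verbs, lexicon = lex)
  expect_equal(g$nodes$name[g$nodes$entity_id == "D1"], "colon cancer")
  extra <- data.frame(doc_id = "d1", start = 0L, end = 4L,
                      surface = "EGFR", entity_id = "G3",
                      category = "gene", source = "gazetteer",
                      stringsAsFactors = FALSE)
  g2 <- assemble_graph(cand, toy_corpus(2), verbs, lexicon = lex,
                       mentions = extra, include_isolated = TRUE)
  expect_true("G3" %in% g2$nodes$entity_id)
  expect_false("G3" %in% c(g2$edges$source, g2$edges$target))
})

test_that("analytics match small-graph expectations", {
  # path query on a 2-node 1-edge graph returns that edge's endpoints
  g2 <- make_random_kg(2, edge_prob = 0, seed = 1)
  e <- g2$edges
  row <- data.frame(source = "N01", target = "N02", label = "binds",
                    tfidf = 1, bio = 1, ambiguity = 1L, weight = 1,
                    support_count = 1L, df = 1L, stringsAsFactors = FALSE)
  row$actions <- list("binds")
  row$provenance <- list(data.frame(doc_id = "docA", sentence_index = 0L,
                                    sentence_text = "s",
                                    stringsAsFactors = FALSE))
  g2 <- knowledge_graph(g2$nodes, rbind(e, row), 1L)
  sp <- kg_shortest_path(g2, "N01", "N02")
  expect_equal(sp$nodes, c("N01", "N02"))
  expect_equal(sp$length, 1)          # 1/weight with weight 1

  # two disjoint triangles: 2 components
  tri <- function(ids) {
    do.call(rbind, lapply(1:3, function(k) {
      a <- ids[k]; b <- ids[k %% 3 + 1]
      row <- data.frame(source = a, target = b, label = "binds",
                        tfidf = 1, bio = 1, ambiguity = 1L, weight = 1,
                        support_count = 1L, df = 1L,
                        stringsAsFactors = FALSE)
      row$actions <- list("binds")
      row$provenance <- list(data.frame(doc_id = "docA",
                                        sentence_index = 0L,
                                        sentence_text = "s",
                                        stringsAsFactors = FALSE))
      row
    }))
  }
  nodes6 <- data.frame(entity_id = c("A", "B", "C", "X", "Y", "Z"),
                       name = letters[1:6], category = "gene",
                       pagerank = NA_real_, stringsAsFactors = FALSE)
  g6 <- knowledge_graph(nodes6, rbind(tri(c("A", "B", "C")),
                                      tri(c("X", "Y", "Z"))), 1L)
  comp <- kg_components(g6)
  expect_equal(max(comp), 2)
  expect_equal(length(unique(comp[c("A", "B", "C")])), 1L)

  # star: center betweenness strictly greater than leaves
  star_edges <- do.call(rbind, lapply(c("B", "C", "D", "E"), function(l) {
    row <- data.frame(source = "HUB", target = l, label = "binds",
                      tfidf = 1, bio = 1, ambiguity = 1L, weight = 1,
                      support_count = 1L, df = 1L, stringsAsFactors = FALSE)
    row$actions <- list("binds")
    row$provenance <- list(data.frame(doc_id = "docA", sentence_index = 0L,
                                      sentence_text = "s",
                                      stringsAsFactors = FALSE))
    row
  }))
  star_nodes <- data.frame(entity_id = c("HUB", "B", "C", "D", "E"),
                           name = 1:5, category = "gene",
                           pagerank = NA_real_, stringsAsFactors = FALSE)
  gs <- knowledge_graph(star_nodes, star_edges, 1L)
  bt <- kg_betweenness(gs)
  expect_true(all(bt["HUB"] > bt[c("B", "C", "D", "E")]))

  # BFS/DFS visit the start's component fully
  expect_setequal(kg_bfs(g6, "A"), c("A", "B", "C"))
  expect_setequal(kg_dfs(g6, "X"), c("X", "Y", "Z"))
  expect_setequal(kg_neighborhood(gs, "HUB", 1), c("HUB", "B", "C", "D", "E"))
  expect_setequal(kg_neighborhood(g6, "A", 1), c("A", "B", "C"))

  # communities separate the triangles
  cm <- kg_communities(g6)
  expect_equal(length(unique(cm[c("A", "B", "C")])), 1L)
  expect_false(cm["A"] == cm["X"])

  # no path across components: empty result, not an error
  sp2 <- kg_shortest_path(g6, "A", "X")
  expect_length(sp2$nodes, 0L)
  expect_equal(sp2$length, Inf)
})

test_that("shortest paths agree with a Dijkstra-free exhaustive oracle", {
  for (seed in 1:8) {
    g <- make_random_kg(6, edge_prob = 0.35, seed = seed + 100)
    e <- g$edges
    if (nrow(e) == 0L) next
    ids <- g$nodes$entity_id
    # oracle: enumerate all simple paths and minimize sum(1/w)
    best_len <- function(a, b) {
      paths <- enumerate_simple_paths_oracle(e, a, b, max_len = 5)
      if (length(paths) == 0L) return(Inf)
      min(vapply(paths, function(p) {
        sum(vapply(seq_len(length(p) - 1L), function(k) {
          sel <- (e$source == p[k] & e$target == p[k + 1]) |
            (e$source == p[k + 1] & e$target == p[k])
          1 / max(e$weight[sel])
        }, numeric(1)))
      }, numeric(1)))
    }
    for (pair in list(c(ids[1], ids[4]), c(ids[2], ids[6]))) {
      expect_equal(kg_shortest_path(g, pair[1], pair[2])$length,
                   best_len(pair[1], pair[2]), tolerance = 1e-12)
    }
  }
})

test_that("gda_recall counts connected gold pairs in either direction", {
  g <- make_random_kg(4, edge_prob = 0, seed = 1)
  row <- data.frame(source = "N01", target = "N02", label = "causes",
                    tfidf = 1, bio = 1, ambiguity = 1L, weight = 1,
                    support_count = 1L, df = 1L, stringsAsFactors = FALSE)
  row$actions <- list("causes")
  row$provenance <- list(data.frame(doc_id = "docA", sentence_index = 0L,
                                    sentence_text = "s",
                                    stringsAsFactors = FALSE))
  g <- knowledge_graph(g$nodes, row, 1L)
  all_in <- data.frame(gene_id = "N01", disease_id = "N02")
  expect_equal(gda_recall(g, all_in), 1)
  # reverse direction still counts
  expect_equal(gda_recall(g, data.frame(gene_id = "N02",
                                        disease_id = "N01")), 1)
  none <- data.frame(gene_id = "N03", disease_id = "N04")
  expect_equal(gda_recall(g, none), 0)
  half <- data.frame(gene_id = c("N01", "N03"),
                     disease_id = c("N02", "N04"))
  expect_equal(gda_recall(g, half), 0.5)
  expect_error(gda_recall(g, half[0, ]), "empty gold")
})
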