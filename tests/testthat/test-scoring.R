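# Edge scores (TF-IDF, edit distance, bio, ambiguity, weight) and
# personalized PageRank.

test_that("tfidf raw scores follow the smoothed log formula", {
  # single edge: min-max degenerates to 1
  expect_equal(compute_tfidf(c(d1 = 1), 1, all_raw = tfidf_raw(1, 1, 1)), 1)

  # two edges, same df, tf 3 vs 1: higher tf normalizes to 1, lower to 0
  raws <- tfidf_raw(c(3, 1), df = c(1, 1), n_docs = 2)
  expect_gt(raws[1], raws[2])
  expect_equal(litkg:::minmax_normalize(raws, raws), c(1, 0))
  # an edge supported in 2 of 2 docs with tf 3 still tops one with tf 1
  raws2 <- c(tfidf_raw(3, 2, 2), tfidf_raw(1, 1, 2))
  expect_equal(compute_tfidf(c(a = 2, b = 1), 2, raws2), 1)

  # equal tf, rarer edge scores strictly higher (idf monotone in df)
  n <- 10
  raw_rare <- tfidf_raw(5, df = 1, n_docs = n)
  raw_everywhere <- tfidf_raw(5, df = n, n_docs = n)
  expect_gt(raw_rare, raw_everywhere)

  # hand recomputation of the formula
  expect_equal(tfidf_raw(3, 2, 7), (1 + log(3)) * (log(8 / 3) + 1))
  expect_error(compute_tfidf(numeric(), 3, raws), "zero support")
})

test_that("normalized edit distance matches the DP oracle", {
  expect_equal(normalized_edit_distance("increase", "increase"), 0)
  expect_equal(normalized_edit_distance("increased", "increase"), 1 / 9)
  expect_equal(normalized_edit_distance("abc", ""), 1)
  expect_equal(normalized_edit_distance("", ""), 0)

  set.seed(99)
  alphabet <- c(letters[1:6], " ")
  rand_str <- function() paste(sample(alphabet, sample(0:12, 1),
                                      replace = TRUE), collapse = "")
  for (k in 1:200) {
    a <- rand_str(); b <- rand_str()
    expect_equal(normalized_edit_distance(a, b),
                 dp_normalized_levenshtein(a, b))
    # symmetry and identity-of-indiscernibles
    expect_equal(normalized_edit_distance(a, b),
                 normalized_edit_distance(b, a))
    if (a != b) expect_gt(normalized_edit_distance(a, b), 0)
  }
  # triangle inequality for the unnormalized core
  for (k in 1:50) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_lte(dp_levenshtein(a, c),
               dp_levenshtein(a, b) + dp_levenshtein(b, c))
  }
})

test_that("bio score is mean best-match similarity, case- and order-invariant", {
  lexicon <- verb_lexicon(c("increase", "inhibit"))
  expect_equal(bio_score("increase", lexicon), 1)
  expect_equal(bio_score("increased", lexicon), 1 - 1 / 9)
  # no shared characters: distance is max length / max length = 1
  expect_equal(dp_normalized_levenshtein("xyzzy", "increase"), 1)
  expect_equal(bio_score("xyzzy", verb_lexicon("increase")), 0)
  expect_equal(bio_score("crease", verb_lexicon("increase")), 1 - 2 / 8)
  expect_equal(bio_score(c("increased", "inhibit"), lexicon),
               mean(c(1 - 1 / 9, 1)))
  expect_equal(bio_score(c("INCREASED"), lexicon),
               bio_score("increased", lexicon))
  expect_equal(bio_score(c("inhibit", "increased"), lexicon),
               bio_score(c("increased", "inhibit"), lexicon))
  expect_error(bio_score(character(), lexicon), "no actions")
  expect_error(bio_score("x", verb_lexicon(character())), "non-empty verb")
})

test_that("ambiguity counts actions and weight follows (t*b)/a", {
  expect_equal(ambiguity("increased"), 1L)
  expect_equal(ambiguity(c("attenuates", "reduces", "facilitates")), 3L)
  expect_equal(ambiguity(list(actions = c("a", "b"))), 2L)

  expect_equal(edge_weight(1, 1, 1), 1)
  expect_equal(edge_weight(0.6, 0.5, 3), 0.1)
  # exact grid
  grid <- expand.grid(t = c(0, 0.25, 0.5, 1), b = c(0, 0.5, 1), a = 1:4)
  expect_equal(edge_weight(grid$t, grid$b, grid$a),
               grid$t * grid$b / grid$a)
  # halving under doubled ambiguity
  expect_equal(edge_weight(0.7, 0.9, 2), edge_weight(0.7, 0.9, 1) / 2)
  # monotonicity on (0,1]
  expect_lt(edge_weight(0.5, 0.5, 2), edge_weight(0.5, 0.5, 1))
  expect_gt(edge_weight(0.6, 0.5, 1), edge_weight(0.5, 0.5, 1))
  expect_gt(edge_weight(0.5, 0.6, 1), edge_weight(0.5, 0.5, 1))
  expect_error(edge_weight(0.5, 0.5, 0), "ambiguity")
})

test_that("personalized PageRank handles base cases exactly", {
  single <- make_random_kg(1, edge_prob = 0)
  expect_equal(unname(personalized_pagerank(single, "N01")), 1)

  # two nodes, symmetric equal-weight edges, teleport both
  two <- make_random_kg(2, edge_prob = 0)
  e <- two$edges
  for (dir in list(c("N01", "N02"), c("N02", "N01"))) {
    row <- data.frame(source = dir[1], target = dir[2], label = "binds",
                      tfidf = 0.5, bio = 1, ambiguity = 1L, weight = 0.5,
                      support_count = 1L, df = 1L, stringsAsFactors = FALSE)
    row$actions <- list("binds")
    row$provenance <- list(data.frame(doc_id = "docA", sentence_index = 0L,
                                      sentence_text = "s",
                                      stringsAsFactors = FALSE))
    e <- rbind(e, row)
  }
  two <- knowledge_graph(two$nodes, e, 1L)
  pr <- personalized_pagerank(two, c("N01", "N02"))
  expect_equal(unname(pr), c(0.5, 0.5))

  # a -> b only, teleport {a}: closed form 0.15/(1-0.85^2) etc.
  ab <- knowledge_graph(two$nodes, e[1, ], 1L)
  pr_ab <- personalized_pagerank(ab, "N01")
  expect_equal(unname(pr_ab), c(0.15 / (1 - 0.85^2),
                                0.85 * 0.15 / (1 - 0.85^2)),
               tolerance = 1e-8)
  expect_equal(unname(round(pr_ab, 4)), c(0.5405, 0.4595))
})

test_that("personalized PageRank matches the dense oracle on random graphs", {
  for (seed in 1:25) {
    g <- make_random_kg(10, edge_prob = 0.25, seed = seed)
    teleport <- if (seed %% 2) character() else c("N01", "N05")
    mine <- personalized_pagerank(g, teleport)
    oracle <- dense_ppr_oracle(g, teleport)
    expect_equal(sum(mine), 1, tolerance = 1e-9)
    expect_true(all(mine >= 0))
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-8)
  }
})

test_that("PageRank approaches the teleport distribution as damping -> 0", {
  g <- make_random_kg(8, edge_prob = 0.4, seed = 17)
  pr <- personalized_pagerank(g, damping = 1e-6)
  expect_equal(unname(pr), rep(1 / 8, 8), tolerance = 1e-5)
  pr2 <- personalized_pagerank(g, c("N02", "N03"), damping = 1e-6)
  expect_equal(unname(pr2[c("N02", "N03")]), c(0.5, 0.5), tolerance = 1e-5)

  # independent cross-check against igraph on a dangling-free graph
  g2 <- make_random_kg(6, edge_prob = 0.9, seed = 23)
  ig <- kg_igraph(g2, collapse = "none", directed = TRUE)
  if (all(igraph::degree(ig, mode = "out") > 0)) {
    ipr <- igraph::page_rank(ig, damping = 0.85,
                             weights = igraph::E(ig)$weight)$vector
    mine <- personalized_pagerank(g2)
    expect_equal(unname(mine[names(ipr)]), unname(ipr), tolerance = 1e-6)
  }
})

test_that("non-convergence is reported with the residual", {
  g <- make_random_kg(5, edge_prob = 0.5, seed = 2)
  expect_error(personalized_pagerank(g, max_iter = 2L),
               "did not converge")
})
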