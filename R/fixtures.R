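# Deterministic synthetic corpora with planted mentions and
# subject-verb-object relations, plus exact gold annotations.
#
# Generation is template-based (never a language model) so gold offsets
# are exact by construction. All stochastic choices are drawn in a
# documented order from R's default Mersenne-Twister stream seeded once
# from the spec, so a given seed reproduces the corpus byte for byte.

#' Example entity lexicon
#'
#' A small built-in lexicon (genes, diseases, processes, drugs) for
#' examples, synthetic corpora and tests.
#'
#' @return An [entity_lexicon()] with 12 entries.
#' @export
example_lexicon <- function() {
  entity_lexicon(
    entity_id = c("G1", "G2", "G3", "G4", "D1", "D2", "D3", "P1", "P2",
                  "C1", "C2", "C3"),
    name = c("TP53", "BRCA1", "EGFR", "circPIP5K1A",
             "colon cancer", "breast cancer", "glioblastoma",
             "apoptosis", "angiogenesis",
             "cisplatin", "tamoxifen", "gefitinib"),
    synonyms = list(c("tumor protein p53", "p53"), c("breast cancer 1"),
                    c("epidermal growth factor receptor"), character(),
                    c("colorectal cancer"), character(), c("GBM"),
                    c("programmed cell death"), character(),
                    character(), character(), character()),
    category = c("gene", "gene", "gene", "gene",
                 "disease", "disease", "disease",
                 "biological_process", "biological_process",
                 "drug", "drug", "drug"))
}

#' Example biological verb-form lexicon
#'
#' A small built-in stand-in for a curated list of biological verb
#' forms.
#'
#' @return A [verb_lexicon()].
#' @export
example_verbs <- function() {
  verb_lexicon(c("activate", "attenuate", "bind", "block", "downregulate",
                 "express", "facilitate", "increase", "induce", "inhibit",
                 "promote", "reduce", "regulate", "suppress", "upregulate"))
}

#' Specification of a synthetic corpus
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_docs Number of documents to generate (>= 0).
#' @param entities An [entity_lexicon()].
#' @param verbs A [verb_lexicon()].
#' @param planted_triples data.frame with columns `source_id`,
#'   `verb_form`, `target_id`, `n_occurrences`; endpoints must be lexicon
#'   ids and verb forms lexicon members.
#' @param distractor_rate Probability of inserting a distractor sentence
#'   (no lexicon terms, no verb forms) after each planted sentence.
#' @param multi_verb_rate Probability that a planted occurrence is
#'   rendered as a multi-verb sentence (three verbs with unannotated
#'   intervening noun phrases, the missing-annotation situation that
#'   motivates the ambiguity penalty).
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_docs, entities, verbs, planted_triples,
                           distractor_rate = 0, multi_verb_rate = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(n_docs), n_docs >= 0,
            inherits(entities, "entity_lexicon"),
            inherits(verbs, "verb_lexicon"),
            is.data.frame(planted_triples),
            all(c("source_id", "verb_form", "target_id",
                  "n_occurrences") %in% names(planted_triples)),
            distractor_rate >= 0, distractor_rate <= 1,
            multi_verb_rate >= 0, multi_verb_rate <= 1)
  bad <- setdiff(c(planted_triples$source_id, planted_triples$target_id),
                 entities$entity_id)
  if (length(bad))
    stop("triple endpoints not in lexicon: ", paste(bad, collapse = ", "),
         call. = FALSE)
  badv <- setdiff(planted_triples$verb_form, as.character(verbs))
  if (length(badv))
    stop("verb forms not in lexicon: ", paste(badv, collapse = ", "),
         call. = FALSE)
  if (any(planted_triples$n_occurrences < 1))
    stop("n_occurrences must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 entities = entities, verbs = verbs,
                 planted_triples = planted_triples,
                 distractor_rate = distractor_rate,
                 multi_verb_rate = multi_verb_rate),
            class = "synthetic_spec")
}

# Distractor vocabulary: screened at generation time against the spec's
# entity surfaces and (de-inflected) verb forms.
.distractor_pool <- list(
  "The laboratory notebook remained on the bench overnight.",
  "Several archive folders were quite dusty.",
  "The corridor outside the unit was silent.",
  "A summary table appears in the appendix.",
  "The committee meeting ran long on Tuesday.",
  "Our courier arrived before noon with new envelopes.")

.filler_nps <- c("the measured response", "the baseline signal",
                 "the assay readout", "the reporter intensity")

# fixed non-entity template words ("<A> <verb> <B> in this experiment.")
.template_tail_tokens <- c("in", "this", "experiment", "and", "daily")

# third-person singular inflection of a base verb form
.inflect_verb <- function(v) {
  if (grepl("(s|sh|ch|x|z|o)$", v)) return(paste0(v, "es"))
  if (grepl("[^aeiou]y$", v)) return(paste0(substr(v, 1, nchar(v) - 1), "ies"))
  paste0(v, "s")
}

# check a distractor sentence contains no lexicon surfaces and no tokens
# de-inflecting to a verb form
.distractor_ok <- function(sentence, gaz_keys, verbs) {
  toks <- tolower(tokenize_words(sentence)$surface)
  if (any(vapply(toks, function(t)
    any(verb_candidates(t) %in% as.character(verbs)), logical(1))))
    return(FALSE)
  low <- normalize_surface(sentence)
  !any(vapply(gaz_keys, function(k) grepl(k, low, fixed = TRUE),
              logical(1)))
}

#' Generate a synthetic corpus with gold annotations
#'
#' Each planted occurrence is rendered as a sentence
#' `"<source surface> <verb> <target surface> in this experiment."`, or
#' (with probability `multi_verb_rate`) as a three-verb sentence with
#' unannotated intervening noun phrases, emulating the
#' missing-annotation case. Occurrences are assigned to documents
#' uniformly at random; distractor sentences are interleaved at
#' `distractor_rate`. Gold records every planted mention span and every
#' planted triple with its action list.
#'
#' Draw order per occurrence: document assignment, multi-verb coin,
#' extra verbs (if multi), surface choices, distractor coin + choice.
#'
#' @param spec A [synthetic_spec()].
#' @return list with `corpus` (a `litkg_corpus`, possibly empty),
#'   `gold_mentions` (mention data.frame, `source = "gold"`),
#'   `gold_triples` (data.frame `doc_id`, `sentence_index`, `source_id`,
#'   `target_id`, `verb_forms` list column, `n_actions`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  empty_triples <- function() {
    df <- data.frame(doc_id = character(), sentence_index = integer(),
                     source_id = character(), target_id = character(),
                     n_actions = integer(), stringsAsFactors = FALSE)
    df$verb_forms <- list()
    df
  }
  if (spec$n_docs == 0L) {
    return(list(corpus = structure(list(documents = list(), n_docs = 0L),
                                   class = "litkg_corpus"),
                gold_mentions = empty_mentions(),
                gold_triples = empty_triples()))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  lex <- spec$entities
  verbs <- as.character(spec$verbs)
  gaz_keys <- normalize_surface(
    unlist(c(lex$name, unlist(lex$synonyms)), use.names = FALSE))
  pool_ok <- vapply(.distractor_pool, .distractor_ok, logical(1),
                    gaz_keys = gaz_keys, verbs = spec$verbs)
  pool <- .distractor_pool[pool_ok]
  if (spec$distractor_rate > 0 && length(pool) == 0L)
    stop("no distractor sentence is free of lexicon terms", call. = FALSE)
  # template constants must not collide with the lexicons either
  fixed_tokens <- c(.template_tail_tokens,
                    tolower(unlist(lapply(.filler_nps,
                                          function(f) tokenize_words(f)$surface))))
  clash <- fixed_tokens[vapply(fixed_tokens, function(t)
    any(verb_candidates(t) %in% verbs) ||
      any(gaz_keys == t), logical(1))]
  if (length(clash))
    stop("template words collide with the lexicons: ",
         paste(unique(clash), collapse = ", "), call. = FALSE)

  surface_of <- function(id) {
    i <- match(id, lex$entity_id)
    forms <- c(lex$name[i], lex$synonyms[[i]])
    forms[sample.int(length(forms), 1L)]
  }
  entity_info <- function(id) {
    i <- match(id, lex$entity_id)
    list(category = lex$category[i])
  }

  # sentence plans per document
  plans <- vector("list", spec$n_docs)
  tr <- spec$planted_triples
  for (t in seq_len(nrow(tr))) {
    for (occ in seq_len(tr$n_occurrences[t])) {
      d <- sample.int(spec$n_docs, 1L)
      multi <- stats::runif(1) < spec$multi_verb_rate
      vmain <- tr$verb_form[t]
      vextra <- if (multi) {
        others <- setdiff(verbs, vmain)
        sample(others, 2L)
      } else character()
      s_surf <- surface_of(tr$source_id[t])
      t_surf <- surface_of(tr$target_id[t])
      plan <- list(kind = "planted", source_id = tr$source_id[t],
                   target_id = tr$target_id[t], verb = vmain,
                   extra = vextra, s_surf = s_surf, t_surf = t_surf)
      plans[[d]] <- c(plans[[d]], list(plan))
      if (stats::runif(1) < spec$distractor_rate) {
        ds <- pool[[sample.int(length(pool), 1L)]]
        plans[[d]] <- c(plans[[d]], list(list(kind = "distractor",
                                              text = ds)))
      }
    }
  }

  docs <- list()
  gm <- list()
  gt <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    sentences <- character()
    offset <- 0L
    sent_idx <- 0L
    doc_plans <- plans[[d]]
    if (length(doc_plans) == 0L) {
      # every document must be non-empty: use a screened distractor or a
      # fixed neutral sentence
      filler <- if (length(pool)) pool[[1L]] else
        "This record is intentionally unannotated."
      doc_plans <- list(list(kind = "distractor", text = filler))
    }
    for (pl in doc_plans) {
      if (pl$kind == "distractor") {
        stext <- pl$text
      } else if (length(pl$extra) == 2L) {
        fill <- .filler_nps[1:2]
        stext <- sprintf("%s %s %s, %s %s, and %s %s daily.",
                         pl$s_surf, .inflect_verb(pl$verb), fill[1],
                         .inflect_verb(pl$extra[1]), fill[2],
                         .inflect_verb(pl$extra[2]), pl$t_surf)
      } else {
        stext <- sprintf("%s %s %s in this experiment.",
                         pl$s_surf, .inflect_verb(pl$verb), pl$t_surf)
      }
      if (pl$kind == "planted") {
        s_start <- offset
        s_end <- s_start + n_codepoints(pl$s_surf)
        t_rel <- .last_occurrence(stext, pl$t_surf)
        t_start <- offset + t_rel
        t_end <- t_start + n_codepoints(pl$t_surf)
        gm[[length(gm) + 1L]] <- data.frame(
          doc_id = doc_id,
          start = c(s_start, t_start), end = c(s_end, t_end),
          surface = c(pl$s_surf, pl$t_surf),
          entity_id = c(pl$source_id, pl$target_id),
          category = c(entity_info(pl$source_id)$category,
                       entity_info(pl$target_id)$category),
          source = "gold", stringsAsFactors = FALSE)
        verb_forms <- c(pl$verb, pl$extra)
        row <- data.frame(doc_id = doc_id, sentence_index = sent_idx,
                          source_id = pl$source_id,
                          target_id = pl$target_id,
                          n_actions = length(verb_forms),
                          stringsAsFactors = FALSE)
        row$verb_forms <- list(verb_forms)
        gt[[length(gt) + 1L]] <- row
      }
      sentences <- c(sentences, stext)
      offset <- offset + n_codepoints(stext) + 1L  # single-space joiner
      sent_idx <- sent_idx + 1L
    }
    docs[[length(docs) + 1L]] <- document(doc_id,
                                          paste(sentences, collapse = " "))
  }
  list(corpus = corpus(docs),
       gold_mentions = if (length(gm)) do.call(rbind, gm)
                       else empty_mentions(),
       gold_triples = if (length(gt)) {
         out <- do.call(rbind, gt); rownames(out) <- NULL; out
       } else empty_triples())
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# 0-based code-point offset of the last occurrence of `needle`
.last_occurrence <- function(haystack, needle) {
  hits <- gregexpr(.rx_escape(needle), haystack, perl = TRUE)[[1]]
  if (hits[1] == -1L) stop("needle not found", call. = FALSE)
  hits[length(hits)] - 1L
}

#' Write a synthetic corpus to disk
#'
#' One `.txt` file per document plus a PubTator-format gold annotation
#' file (`gold.pubtator`) carrying the planted mentions.
#'
#' @param generated Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in generated$corpus$documents) {
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")),
               useBytes = TRUE)
  }
  con <- file(file.path(dir, "gold.pubtator"), open = "wt",
              encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  gm <- generated$gold_mentions
  for (doc in generated$corpus$documents) {
    writeLines(paste0(doc$doc_id, "|t|", doc$text), con)
    rows <- gm[gm$doc_id == doc$doc_id, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      writeLines(paste(rows$doc_id[i], rows$start[i], rows$end[i],
                       rows$surface[i], rows$category[i],
                       rows$entity_id[i], sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(dir)
}
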