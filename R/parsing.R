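# Sentence splitting and per-sentence token/PoS/dependency structures.
#
# Parsing goes through a pluggable engine contract so that the downstream
# relation extraction is independent of any one NLP toolkit. The bundled
# engine is a deterministic rule-based parser: tokenization by regular
# expression, verb tagging by lookup in a biological verb-form lexicon
# (with inflectional suffix handling), and a verb-chain dependency tree.
# A statistical parser can be registered with the same contract via
# register_parser_engine().

.parser_registry <- new.env(parent = emptyenv())

#' Register a parser engine
#'
#' An engine is a function `f(sentence_text, doc_id, sentence_index,
#' char_offset, verbs)` returning a `sentence_parse`. Registered engines
#' are selected by name in [parse_sentence()] and [parse_document()].
#'
#' @param name Engine name (config key `parser.engine`).
#' @param fn Engine function.
#' @export
register_parser_engine <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .parser_registry)
  invisible(name)
}

#' List registered parser engines
#' @return Character vector of engine names.
#' @export
parser_engines <- function() sort(ls(.parser_registry))

#' Split a document into sentences
#'
#' Rule-based splitting: a run of `.!?` ends a sentence when followed by
#' whitespace and an alphanumeric or opening quote/bracket (or end of
#' text), unless the preceding token is a whitelisted abbreviation or
#' contains an internal period.
#' Spans are 0-based half-open code-point offsets into the document text,
#' trimmed of surrounding whitespace; they are disjoint, ordered, and
#' cover all non-whitespace text.
#'
#' @param doc A [document()] or a single string.
#' @return data.frame with columns `sentence_index` (0-based), `start`,
#'   `end`.
#' @export
split_sentences <- function(doc) {
  text <- if (inherits(doc, "litkg_document")) doc$text else doc
  stopifnot(is.character(text), length(text) == 1L)
  abbrev <- c("e.g", "i.e", "al", "fig", "figs", "dr", "vs", "cf", "no",
              "etc", "approx", "ca", "st")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L || !nzchar(trimws(text))) {
    return(data.frame(sentence_index = integer(), start = integer(),
                      end = integer()))
  }
  boundaries <- integer()  # positions (1-based) after which a sentence ends
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      # token immediately before the terminator
      k <- i - 1L
      word <- character()
      while (k >= 1L && grepl("[[:alnum:].]", chars[k])) {
        word <- c(chars[k], word); k <- k - 1L
      }
      prev_tok <- tolower(paste(word, collapse = ""))
      # whitelist plus tokens with internal periods ("e.g", "i.v")
      is_abbrev <- chars[i] == "." &&
        (prev_tok %in% abbrev || grepl("\\.", prev_tok))
      # followed by whitespace + sentence-initial character, or end of text
      m <- j + 1L
      while (m <= n && grepl("[[:space:]]", chars[m])) m <- m + 1L
      # next sentence may open with a lowercase entity name (p53,
      # circPIP5K1A), so any alphanumeric counts as sentence-initial
      follows_ok <- m > n ||
        (m > j + 1L && grepl("[[:alnum:]\"'(“]", chars[m]))
      if (!is_abbrev && follows_ok) boundaries <- c(boundaries, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cut_ends <- unique(c(boundaries, n))
  spans <- list()
  seg_start <- 1L
  for (b in cut_ends) {
    s <- seg_start; e <- b
    while (s <= e && grepl("[[:space:]]", chars[s])) s <- s + 1L
    while (e >= s && grepl("[[:space:]]", chars[e])) e <- e - 1L
    if (s <= e) spans[[length(spans) + 1L]] <- c(s - 1L, e)
    seg_start <- b + 1L
  }
  if (length(spans) == 0L) {
    return(data.frame(sentence_index = integer(), start = integer(),
                      end = integer()))
  }
  m <- do.call(rbind, spans)
  data.frame(sentence_index = seq_len(nrow(m)) - 1L,
             start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Candidate dictionary forms for an inflected token: the form itself plus
# de-inflections of -s/-es/-ies, -ed (silent e, consonant doubling, -ied)
# and -ing (silent e, consonant doubling).
verb_candidates <- function(lower) {
  cands <- lower
  nc <- nchar(lower)
  undouble <- function(stem) {
    k <- nchar(stem)
    if (k >= 2L && substr(stem, k, k) == substr(stem, k - 1L, k - 1L) &&
        grepl("[^aeiou]", substr(stem, k, k)))
      substr(stem, 1L, k - 1L)
    else NULL
  }
  if (nc > 1L && endsWith(lower, "s") && !endsWith(lower, "ss")) {
    cands <- c(cands, substr(lower, 1L, nc - 1L))
    if (nc > 2L && endsWith(lower, "es"))
      cands <- c(cands, substr(lower, 1L, nc - 2L))
    if (nc > 3L && endsWith(lower, "ies"))
      cands <- c(cands, paste0(substr(lower, 1L, nc - 3L), "y"))
  }
  if (nc > 2L && endsWith(lower, "ed")) {
    stem <- substr(lower, 1L, nc - 2L)
    cands <- c(cands, stem, paste0(stem, "e"), undouble(stem))
    if (endsWith(lower, "ied"))
      cands <- c(cands, paste0(substr(lower, 1L, nc - 3L), "y"))
  }
  if (nc > 3L && endsWith(lower, "ing")) {
    stem <- substr(lower, 1L, nc - 3L)
    cands <- c(cands, stem, paste0(stem, "e"), undouble(stem))
  }
  unique(cands)
}

#' Deterministic rule-based sentence parse
#'
#' Tokenizes on words and punctuation, tags a token `VERB` iff one of its
#' de-inflected forms is in the verb lexicon (`PUNCT` for punctuation,
#' `X` otherwise), and builds a verb-chain dependency tree: the first verb
#' is the root, each later verb attaches to the previous verb (`conj`),
#' and every other token attaches to the nearest preceding verb (or the
#' first verb, or token 0 when the sentence has no verb).
#'
#' @param sentence_text Sentence string.
#' @param verbs A [verb_lexicon()].
#' @param doc_id,sentence_index,char_offset Provenance: document id,
#'   0-based sentence index, and the code-point offset of the sentence
#'   within the document (token spans are document-level).
#' @return A `sentence_parse`: list with `doc_id`, `sentence_index`,
#'   `start`, `end`, and `tokens` (data.frame `index`, `surface`, `lemma`,
#'   `pos`, `head_index`, `deprel`, `start`, `end`).
#' @export
fallback_parse <- function(sentence_text, verbs,
                           doc_id = "doc", sentence_index = 0L,
                           char_offset = 0L) {
  toks <- tokenize_full(sentence_text)
  nt <- nrow(toks)
  if (nt == 0L) stop("cannot parse empty sentence", call. = FALSE)
  lower <- tolower(toks$surface)
  is_punct <- grepl("^[^[:alnum:]]$", toks$surface)
  lemma <- lower
  pos <- ifelse(is_punct, "PUNCT", "X")
  vset <- as.character(verbs)
  for (i in seq_len(nt)) {
    if (is_punct[i]) next
    hit <- intersect(verb_candidates(lower[i]), vset)
    if (length(hit)) {
      pos[i] <- "VERB"
      lemma[i] <- hit[1]
    }
  }
  verb_idx <- which(pos == "VERB")
  head_index <- integer(nt)
  deprel <- character(nt)
  if (length(verb_idx) == 0L) {
    head_index <- rep(1L, nt)
    head_index[1L] <- 1L
    deprel <- rep("dep", nt)
    deprel[1L] <- "ROOT"
  } else {
    root <- verb_idx[1L]
    for (i in seq_len(nt)) {
      if (i == root) { head_index[i] <- i; deprel[i] <- "ROOT"; next }
      if (pos[i] == "VERB") {
        head_index[i] <- verb_idx[max(which(verb_idx < i))]
        deprel[i] <- "conj"
      } else {
        prev <- verb_idx[verb_idx < i]
        head_index[i] <- if (length(prev)) prev[length(prev)] else root
        deprel[i] <- "dep"
      }
    }
  }
  parse <- structure(list(
    doc_id = doc_id, sentence_index = as.integer(sentence_index),
    start = as.integer(char_offset), end = as.integer(char_offset) + n_codepoints(sentence_text),
    tokens = data.frame(index = seq_len(nt) - 1L, surface = toks$surface,
                        lemma = lemma, pos = pos,
                        head_index = head_index - 1L, deprel = deprel,
                        start = toks$start + as.integer(char_offset),
                        end = toks$end + as.integer(char_offset),
                        stringsAsFactors = FALSE)),
    class = "sentence_parse")
  validate_sentence_parse(parse)
  parse
}

#' Validate a sentence parse
#'
#' Checks the structural invariants: valid head indices, exactly one root
#' (a token heading itself), acyclic arcs forming a tree, and ordered
#' non-overlapping token spans inside the sentence span.
#'
#' @param parse A `sentence_parse`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_sentence_parse <- function(parse) {
  tk <- parse$tokens
  n <- nrow(tk)
  stopifnot(n >= 1L)
  if (any(tk$head_index < 0L | tk$head_index >= n))
    stop("invalid head_index", call. = FALSE)
  roots <- which(tk$head_index == tk$index)
  if (length(roots) != 1L)
    stop("parse must have exactly one root, found ", length(roots),
         call. = FALSE)
  # acyclicity: every token reaches the root
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (tk$head_index[j] + 1L != j) {
      if (seen[j]) stop("cycle in dependency arcs", call. = FALSE)
      seen[j] <- TRUE
      j <- tk$head_index[j] + 1L
    }
  }
  if (n > 1L && any(diff(tk$start) <= 0))
    stop("token spans out of order", call. = FALSE)
  if (any(tk$start < parse$start | tk$end > parse$end))
    stop("token spans outside sentence span", call. = FALSE)
  if (n > 1L && any(tk$start[-1L] < tk$end[-n]))
    stop("overlapping token spans", call. = FALSE)
  invisible(TRUE)
}

#' Parse one sentence with a registered engine
#'
#' @param sentence_text Sentence string.
#' @param verbs A [verb_lexicon()] (used by the rule-based engine).
#' @param engine Engine name; see [parser_engines()].
#' @param doc_id,sentence_index,char_offset Provenance passed to the
#'   engine.
#' @return A validated `sentence_parse`.
#' @export
parse_sentence <- function(sentence_text, verbs, engine = "fallback",
                           doc_id = "doc", sentence_index = 0L,
                           char_offset = 0L) {
  if (!nzchar(trimws(sentence_text)))
    stop("cannot parse empty sentence", call. = FALSE)
  fn <- get0(engine, envir = .parser_registry)
  if (is.null(fn))
    stop("unknown parser engine: ", engine, " (registered: ",
         paste(parser_engines(), collapse = ", "), ")", call. = FALSE)
  parse <- tryCatch(
    fn(sentence_text, doc_id = doc_id, sentence_index = sentence_index,
       char_offset = char_offset, verbs = verbs),
    error = function(e) stop("parse error in sentence ", sentence_index,
                             " of ", doc_id, ": ", conditionMessage(e),
                             call. = FALSE))
  validate_sentence_parse(parse)
  parse
}

#' Parse all sentences of a document
#'
#' @param doc A [document()].
#' @inheritParams parse_sentence
#' @return List of `sentence_parse`, one per sentence (in order).
#' @export
parse_document <- function(doc, verbs, engine = "fallback") {
  sents <- split_sentences(doc)
  lapply(seq_len(nrow(sents)), function(i) {
    parse_sentence(slice_text(doc$text, sents$start[i], sents$end[i]),
                   verbs = verbs, engine = engine, doc_id = doc$doc_id,
                   sentence_index = sents$sentence_index[i],
                   char_offset = sents$start[i])
  })
}

# Register the bundled engine at load time.
.onLoad <- function(libname, pkgname) {
  register_parser_engine("fallback", function(sentence_text, doc_id,
                                              sentence_index, char_offset,
                                              verbs) {
    fallback_parse(sentence_text, verbs, doc_id = doc_id,
                   sentence_index = sentence_index,
                   char_offset = char_offset)
  })
}
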