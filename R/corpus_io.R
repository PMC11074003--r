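# Readers and writers: plain-text corpora, PubTator-format annotated
# abstracts, entity/verb lexicons, and GraphML/JSON graph export.

#' Construct a document
#'
#' A document is the atomic unit of a corpus: an identifier plus UTF-8 text.
#'
#' @param doc_id Non-empty string identifier, unique within a corpus.
#' @param text Non-empty UTF-8 text.
#' @param source_kind `"plain_text"` or `"pubtator"`.
#' @param metadata Optional named list of string metadata (title, year, ...).
#' @return An object of class `litkg_document`.
#' @export
document <- function(doc_id, text, source_kind = "plain_text",
                     metadata = list()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L, nzchar(text))
  if (!source_kind %in% c("plain_text", "pubtator"))
    stop("source_kind must be 'plain_text' or 'pubtator'", call. = FALSE)
  structure(list(doc_id = doc_id, text = enc2utf8(text),
                 source_kind = source_kind, metadata = metadata),
            class = "litkg_document")
}

#' Construct a corpus from documents
#'
#' @param documents List of [document()] objects with unique `doc_id`s.
#' @return An object of class `litkg_corpus` with fields `documents`
#'   (named by doc_id) and `n_docs`.
#' @export
corpus <- function(documents) {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", ids[duplicated(ids)][1], call. = FALSE)
  names(documents) <- ids
  structure(list(documents = documents, n_docs = length(documents)),
            class = "litkg_corpus")
}

#' @export
print.litkg_corpus <- function(x, ...) {
  cat(sprintf("<litkg_corpus> %d document(s)\n", x$n_docs))
  ids <- names(x$documents)
  show <- utils::head(ids, 5)
  cat("  ", paste(show, collapse = ", "),
      if (length(ids) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a plain-text corpus
#'
#' Reads one document per file (UTF-8). `doc_id` is the file stem.
#'
#' @param path A directory of text files, or a single text file.
#' @param pattern Filename filter used when `path` is a directory.
#' @return A `litkg_corpus`.
#' @export
read_text_corpus <- function(path, pattern = "\\.txt$") {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = pattern, full.names = TRUE))
  } else {
    path
  }
  if (length(files) == 0L)
    stop("no documents found under ", path, call. = FALSE)
  docs <- lapply(files, function(f) {
    txt <- tryCatch(
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
      error = function(e) stop("cannot decode ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    if (!all(validEnc(txt)))
      stop("file is not valid UTF-8: ", f, call. = FALSE)
    if (!nzchar(trimws(txt))) stop("empty document: ", f, call. = FALSE)
    document(doc_id = sub("\\.[^.]*$", "", basename(f)), text = txt)
  })
  corpus(docs)
}

#' Read a PubTator-format file
#'
#' Parses the PubTator exchange dialect: `PMID|t|<title>` and
#' `PMID|a|<abstract>` lines followed by tab-separated annotation lines
#' `PMID <TAB> start <TAB> end <TAB> text <TAB> type <TAB> id`, records
#' separated by blank lines. Document text is `title + " " + abstract`;
#' annotation offsets index that concatenation (0-based, half-open, code
#' points).
#'
#' @param path Path to the PubTator file.
#' @param type_map Optional named character vector mapping PubTator entity
#'   types to the configured category labels (e.g.
#'   `c(Gene = "gene", Disease = "disease")`). Unmapped types are kept
#'   verbatim.
#' @return A list with elements `corpus` (a `litkg_corpus`) and `mentions`
#'   (a mention data.frame with `source = "pubtator"`).
#' @export
read_pubtator <- function(path, type_map = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  mention_rows <- list()
  title <- abstract <- NULL
  cur_id <- NULL

  flush_record <- function() {
    if (is.null(cur_id)) return()
    txt <- paste(c(title, abstract), collapse = " ")
    if (!nzchar(txt)) stop("record ", cur_id, " has empty text", call. = FALSE)
    docs[[length(docs) + 1L]] <<- document(cur_id, txt,
                                           source_kind = "pubtator",
                                           metadata = list(title = title %||% ""))
    title <<- abstract <<- NULL
    cur_id <<- NULL
  }

  pending <- list()  # annotation lines per record, validated after text known
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush_record(); next }
    tm <- regmatches(ln, regexec("^([^|\t]+)\\|t\\|(.*)$", ln))[[1]]
    am <- regmatches(ln, regexec("^([^|\t]+)\\|a\\|(.*)$", ln))[[1]]
    if (length(tm) == 3L) {
      flush_record()
      cur_id <- tm[2]; title <- tm[3]
    } else if (length(am) == 3L) {
      if (is.null(cur_id)) cur_id <- am[2]
      abstract <- am[3]
    } else if (grepl("\t", ln, fixed = TRUE)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 6L)
        stop(sprintf("malformed annotation line %d (expected 6 tab-separated fields, got %d): %s",
                     i, length(f), ln), call. = FALSE)
      txt <- paste(c(title, abstract), collapse = " ")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end))
        stop("non-integer offsets on line ", i, ": ", ln, call. = FALSE)
      if (end <= start)
        stop("end <= start on line ", i, ": ", ln, call. = FALSE)
      if (start < 0L || end > n_codepoints(txt))
        stop(sprintf("offsets [%d,%d) outside text (length %d) on line %d: %s",
                     start, end, n_codepoints(txt), i, ln), call. = FALSE)
      surf <- slice_text(txt, start, end)
      if (surf != f[4])
        stop(sprintf("surface mismatch on line %d: file says %s, text slice is %s",
                     i, dQuote(f[4]), dQuote(surf)), call. = FALSE)
      cat_lab <- f[5]
      if (!is.null(type_map) && cat_lab %in% names(type_map))
        cat_lab <- unname(type_map[cat_lab])
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        doc_id = f[1], start = start, end = end, surface = surf,
        entity_id = f[6], category = cat_lab, source = "pubtator",
        stringsAsFactors = FALSE)
    } else {
      stop("unrecognized line ", i, ": ", ln, call. = FALSE)
    }
  }
  flush_record()
  if (length(docs) == 0L) stop("no PubTator records found in ", path,
                               call. = FALSE)
  mentions <- if (length(mention_rows)) do.call(rbind, mention_rows)
              else empty_mentions()
  list(corpus = corpus(docs), mentions = mentions)
}

#' Read an entity lexicon (TSV)
#'
#' Expects four tab-separated columns: `id`, `name`, `synonyms`
#' (`|`-separated, may be empty), `category`. A header row with exactly
#' those names is skipped if present.
#'
#' @param path Path to the TSV file.
#' @param categories Optional character vector of allowed category labels;
#'   rows with other categories raise an error. `NULL` accepts any label.
#' @return An `entity_lexicon`: a data.frame with columns `entity_id`,
#'   `name`, `synonyms` (list column), `category`.
#' @export
read_entity_lexicon <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[1]),
                                 "id\tname\tsynonyms\tcategory"))
    lines <- lines[-1]
  if (length(lines) == 0L) stop("empty lexicon file: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != 4L)
  if (length(bad))
    stop("lexicon row ", bad[1], " does not have 4 tab-separated fields",
         call. = FALSE)
  entity_lexicon(
    entity_id = vapply(rows, `[`, character(1), 1L),
    name = vapply(rows, `[`, character(1), 2L),
    synonyms = lapply(rows, function(r) {
      s <- strsplit(r[3], "|", fixed = TRUE)[[1]]
      s[nzchar(s)]
    }),
    category = vapply(rows, `[`, character(1), 4L),
    categories = categories)
}

#' Construct an entity lexicon programmatically
#'
#' @param entity_id,name,category Character vectors of equal length.
#' @param synonyms List of character vectors (one per entry; may be empty).
#' @param categories Optional allowed category set (see
#'   [read_entity_lexicon()]).
#' @return An `entity_lexicon` data.frame.
#' @export
entity_lexicon <- function(entity_id, name, synonyms = NULL,
                           category, categories = NULL) {
  if (is.null(synonyms)) synonyms <- rep(list(character()), length(entity_id))
  if (length(category) == 1L) category <- rep(category, length(entity_id))
  stopifnot(length(entity_id) == length(name),
            length(entity_id) == length(category),
            length(entity_id) == length(synonyms))
  if (length(entity_id) == 0L) stop("empty lexicon", call. = FALSE)
  if (anyDuplicated(entity_id))
    stop("duplicate entity_id in lexicon: ",
         entity_id[duplicated(entity_id)][1], call. = FALSE)
  if (!is.null(categories)) {
    unknown <- setdiff(unique(category), categories)
    if (length(unknown))
      stop("unknown category: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  lex <- data.frame(entity_id = entity_id, name = name,
                    category = category, stringsAsFactors = FALSE)
  lex$synonyms <- synonyms
  attr(lex, "categories") <- categories %||% sort(unique(category))
  class(lex) <- c("entity_lexicon", "data.frame")
  lex
}

#' Read a biological verb-form lexicon
#'
#' One verb form per line; case-folded and deduplicated. Stands in for a
#' curated list of biological verb forms used by the bio score.
#'
#' @param path Path to the text file.
#' @param allow_empty Permit an empty file (bio scoring then unavailable).
#' @return A `verb_lexicon`: a character vector of lowercase forms.
#' @export
read_verb_lexicon <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  v <- readLines(path, encoding = "UTF-8", warn = FALSE)
  v <- unique(tolower(trimws(v)))
  v <- v[nzchar(v)]
  if (length(v) == 0L && !allow_empty)
    stop("empty verb lexicon: ", path, call. = FALSE)
  verb_lexicon(v)
}

#' Construct a verb lexicon programmatically
#' @param forms Character vector of verb forms.
#' @return A `verb_lexicon` (lowercase, deduplicated).
#' @export
verb_lexicon <- function(forms) {
  v <- unique(tolower(trimws(as.character(forms))))
  v <- v[nzchar(v)]
  structure(v, class = "verb_lexicon")
}

#' Write a knowledge graph to GraphML or JSON
#'
#' GraphML carries node attributes (`entity_id`, `name`, `category`,
#' `pagerank`) and edge attributes (`label`, `actions`, `tfidf`, `bio`,
#' `ambiguity`, `weight`, `support_count`, `df`). JSON additionally carries
#' full sentence provenance `(doc_id, sentence_index, sentence_text)` per
#' edge and round-trips exactly through [read_knowledge_graph()].
#'
#' @param graph A `knowledge_graph`.
#' @param path Output file path.
#' @param format `"graphml"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_knowledge_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "knowledge_graph"))
  if (format == "json") {
    edges <- graph$edges
    payload <- list(
      n_docs = graph$n_docs,
      nodes = graph$nodes,
      edges = lapply(seq_len(nrow(edges)), function(i) {
        e <- edges[i, ]
        list(source = e$source, target = e$target, label = e$label,
             actions = e$actions[[1]], tfidf = e$tfidf, bio = e$bio,
             ambiguity = e$ambiguity, weight = e$weight,
             support_count = e$support_count, df = e$df,
             provenance = e$provenance[[1]])
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    ig <- kg_igraph(graph, collapse = "none", directed = TRUE)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read a knowledge graph written by [write_knowledge_graph()]
#'
#' @param path Input file path.
#' @param format `"json"` or `"graphml"`.
#' @return A `knowledge_graph`. GraphML input restores all scores but has
#'   empty provenance (GraphML does not carry it).
#' @export
read_knowledge_graph <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "json") {
    p <- jsonlite::read_json(path, simplifyVector = FALSE)
    nodes <- data.frame(
      entity_id = vapply(p$nodes, function(n) n$entity_id, character(1)),
      name = vapply(p$nodes, function(n) n$name, character(1)),
      category = vapply(p$nodes, function(n) n$category, character(1)),
      pagerank = vapply(p$nodes, function(n) as.numeric(n$pagerank),
                        numeric(1)),
      stringsAsFactors = FALSE)
    edges <- data.frame(
      source = vapply(p$edges, function(e) e$source, character(1)),
      target = vapply(p$edges, function(e) e$target, character(1)),
      label = vapply(p$edges, function(e) e$label, character(1)),
      tfidf = vapply(p$edges, function(e) as.numeric(e$tfidf), numeric(1)),
      bio = vapply(p$edges, function(e) as.numeric(e$bio), numeric(1)),
      ambiguity = vapply(p$edges, function(e) as.integer(e$ambiguity),
                         integer(1)),
      weight = vapply(p$edges, function(e) as.numeric(e$weight), numeric(1)),
      support_count = vapply(p$edges, function(e) as.integer(e$support_count),
                             integer(1)),
      df = vapply(p$edges, function(e) as.integer(e$df), integer(1)),
      stringsAsFactors = FALSE)
    edges$actions <- lapply(p$edges, function(e)
      as.character(unlist(e$actions, use.names = FALSE)))
    edges$provenance <- lapply(p$edges, function(e) {
      if (length(e$provenance) == 0L) return(empty_provenance())
      data.frame(
        doc_id = vapply(e$provenance, function(pr) pr$doc_id, character(1)),
        sentence_index = vapply(e$provenance,
                                function(pr) as.integer(pr$sentence_index),
                                integer(1)),
        sentence_text = vapply(e$provenance, function(pr) pr$sentence_text,
                               character(1)),
        stringsAsFactors = FALSE)
    })
    knowledge_graph(nodes = nodes, edges = edges,
                    n_docs = as.integer(p$n_docs))
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
      entity_id = igraph::vertex_attr(ig, "name"),
      name = igraph::vertex_attr(ig, "entity_name"),
      category = igraph::vertex_attr(ig, "category"),
      pagerank = igraph::vertex_attr(ig, "pagerank"),
      stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(ig, names = TRUE)
    edges <- data.frame(
      source = el[, 1], target = el[, 2],
      label = igraph::edge_attr(ig, "label"),
      tfidf = igraph::edge_attr(ig, "tfidf"),
      bio = igraph::edge_attr(ig, "bio"),
      ambiguity = as.integer(igraph::edge_attr(ig, "ambiguity")),
      weight = igraph::edge_attr(ig, "weight"),
      support_count = as.integer(igraph::edge_attr(ig, "support_count")),
      df = as.integer(igraph::edge_attr(ig, "df")),
      stringsAsFactors = FALSE)
    edges$actions <- strsplit(igraph::edge_attr(ig, "actions") %||%
                                character(nrow(edges)), "; ", fixed = TRUE)
    edges$provenance <- rep(list(empty_provenance()), nrow(edges))
    knowledge_graph(nodes = nodes, edges = edges,
                    n_docs = as.integer(igraph::graph_attr(ig, "n_docs")))
  }
}
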