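# Gazetteer entity linking: dictionary NER over a lexicon, merging of
# annotation sources, and precision/recall/F1 evaluation.
#
# The gazetteer is a deliberately minimal linker: case-insensitive,
# longest-match, token-boundary-aligned dictionary lookup. Contextual
# disambiguation and abbreviation expansion are out of scope.

#' Build a gazetteer from an entity lexicon
#'
#' Indexes every canonical name and synonym under a normalized key
#' (case-folded, internal whitespace collapsed). Collisions between
#' different entities on the same surface form are resolved in favour of
#' the lexicographically smallest `entity_id` and reported as a warning.
#'
#' @param lexicon An `entity_lexicon` (see [entity_lexicon()]).
#' @return A `gazetteer` object.
#' @export
build_gazetteer <- function(lexicon) {
  stopifnot(inherits(lexicon, "entity_lexicon"))
  if (nrow(lexicon) == 0L) stop("empty lexicon", call. = FALSE)
  forms <- do.call(rbind, lapply(seq_len(nrow(lexicon)), function(i) {
    surfs <- unique(c(lexicon$name[i], lexicon$synonyms[[i]]))
    data.frame(key = normalize_surface(surfs),
               entity_id = lexicon$entity_id[i],
               category = lexicon$category[i],
               stringsAsFactors = FALSE)
  }))
  forms <- forms[nzchar(forms$key), , drop = FALSE]
  if (nrow(forms) == 0L) stop("lexicon has no usable surface forms",
                              call. = FALSE)
  # deterministic collision resolution: smallest entity_id per key
  forms <- unique(forms)
  forms <- forms[order(forms$key, forms$entity_id), , drop = FALSE]
  clash <- unique(forms$key[duplicated(forms$key)])
  if (length(clash))
    warning("gazetteer key collision (smallest entity_id kept): ",
            paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  forms <- forms[!duplicated(forms$key), , drop = FALSE]
  max_len <- max(vapply(strsplit(forms$key, " ", fixed = TRUE),
                        length, integer(1)))
  structure(list(keys = forms$key, entity_id = forms$entity_id,
                 category = forms$category, max_form_len = max_len),
            class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer> %d surface forms, %d entities, max form length %d tokens\n",
              length(x$keys), length(unique(x$entity_id)), x$max_form_len))
  invisible(x)
}

#' Annotate a document with gazetteer mentions
#'
#' Greedy longest-match, leftmost-first scan aligned to word-token
#' boundaries; matching is case-insensitive with whitespace collapsed.
#' Output mentions never overlap.
#'
#' @param doc A [document()].
#' @param gaz A [build_gazetteer()] result.
#' @return A mention data.frame (`doc_id`, `start`, `end`, `surface`,
#'   `entity_id`, `category`, `source = "gazetteer"`), sorted by `start`.
#'   Offsets are 0-based half-open code points into the document text.
#' @export
annotate <- function(doc, gaz) {
  stopifnot(inherits(doc, "litkg_document"), inherits(gaz, "gazetteer"))
  toks <- tokenize_words(doc$text)
  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(gaz$max_form_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      key <- normalize_surface(slice_text(doc$text, toks$start[i], toks$end[j]))
      hit <- match(key, gaz$keys)
      if (!is.na(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          doc_id = doc$doc_id, start = toks$start[i], end = toks$end[j],
          surface = slice_text(doc$text, toks$start[i], toks$end[j]),
          entity_id = gaz$entity_id[hit], category = gaz$category[hit],
          source = "gazetteer", stringsAsFactors = FALSE)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

#' Merge mention collections from two annotation sources
#'
#' Takes the set union of two mention collections over the same documents.
#' Where two mentions overlap in span, the longer span is kept; for equal
#' spans the higher-priority source wins. The kept mention's `source` is
#' preserved and a `merged` flag marks spans found identically in both
#' inputs.
#'
#' @param a,b Mention data.frames.
#' @param priority Character vector of source labels, highest priority
#'   first; sources not listed rank below listed ones.
#' @return A merged mention data.frame sorted by `doc_id`, `start`.
#' @export
merge_annotations <- function(a, b, priority = c("pubtator", "gazetteer")) {
  if (nrow(a) == 0L && nrow(b) == 0L) {
    out <- empty_mentions(); out$merged <- logical(); return(out)
  }
  all_m <- rbind(a[, names(empty_mentions())], b[, names(empty_mentions())])
  key <- paste(all_m$doc_id, all_m$start, all_m$end)
  in_a <- key %in% paste(a$doc_id, a$start, a$end)
  in_b <- key %in% paste(b$doc_id, b$start, b$end)
  all_m$merged <- in_a & in_b
  prio <- match(all_m$source, priority)
  prio[is.na(prio)] <- length(priority) + 1L
  len <- all_m$end - all_m$start
  # greedy: longest span first, then priority, then position, then entity id
  ord <- order(all_m$doc_id, -len, prio, all_m$start, all_m$entity_id)
  all_m <- all_m[ord, , drop = FALSE]
  kept <- list()
  occupied <- list()  # per doc: matrix of kept spans
  for (i in seq_len(nrow(all_m))) {
    d <- all_m$doc_id[i]
    sp <- occupied[[d]]
    s <- all_m$start[i]; e <- all_m$end[i]
    if (!is.null(sp) && any(spans_overlap(s, e, sp[, 1], sp[, 2]))) next
    # drop exact duplicates of already-kept spans (same doc/start/end)
    occupied[[d]] <- rbind(sp, c(s, e))
    kept[[length(kept) + 1L]] <- all_m[i, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$doc_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate NER predictions against a gold standard
#'
#' `exact` mode requires identical `(doc_id, start, end)`; `overlap` mode
#' counts a gold mention as recalled if any prediction overlaps it (and a
#' prediction as correct if it overlaps any gold mention). Zero
#' denominators yield 0 by convention.
#'
#' @param predicted,gold Mention data.frames.
#' @param mode `"exact"` or `"overlap"`.
#' @return A named list: `precision`, `recall`, `f1`, `tp_pred`, `tp_gold`.
#' @export
evaluate_ner <- function(predicted, gold, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  np <- nrow(predicted); ng <- nrow(gold)
  if (mode == "exact") {
    pk <- paste(predicted$doc_id, predicted$start, predicted$end)
    gk <- paste(gold$doc_id, gold$start, gold$end)
    tp_pred <- sum(pk %in% gk)
    tp_gold <- sum(gk %in% pk)
  } else {
    hit_pred <- logical(np)
    hit_gold <- logical(ng)
    if (np > 0L && ng > 0L) {
      for (i in seq_len(np)) {
        same <- gold$doc_id == predicted$doc_id[i] &
          spans_overlap(predicted$start[i], predicted$end[i],
                        gold$start, gold$end)
        if (any(same)) { hit_pred[i] <- TRUE; hit_gold[same] <- TRUE }
      }
    }
    tp_pred <- sum(hit_pred)
    tp_gold <- sum(hit_gold)
  }
  precision <- if (np == 0L) 0 else tp_pred / np
  recall <- if (ng == 0L) 0 else tp_gold / ng
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp_pred = tp_pred, tp_gold = tp_gold)
}
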