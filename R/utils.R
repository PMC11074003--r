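# Internal helpers shared across modules.
#
# All character offsets in this package are 0-based, half-open intervals
# over Unicode code points (PubTator convention), never bytes.

# Slice text[start:end) with 0-based half-open code-point offsets.
slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

n_codepoints <- function(text) nchar(text, type = "chars")

# Surface-form normalization used by the gazetteer and lexicon indexing:
# case-fold and collapse runs of whitespace to a single space.
normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Word-token regex: alphanumeric runs, allowing internal hyphens and
# apostrophes ("circPIP5K1A", "alpha-2", "won't").
.word_rx <- "[[:alnum:]]+(?:[-'’][[:alnum:]]+)*"

# Tokenize into word tokens only (used by the gazetteer scan).
# Returns a data.frame with 0-based half-open char spans.
tokenize_words <- function(text) {
  m <- gregexpr(.word_rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# Tokenize into word + punctuation tokens (used by the rule-based parser).
tokenize_full <- function(text) {
  rx <- paste0(.word_rx, "|[^[:space:][:alnum:]]")
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# Empty mention frame; the single mention container used package-wide.
empty_mentions <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             surface = character(), entity_id = character(),
             category = character(), source = character(),
             stringsAsFactors = FALSE)
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

`%||%` <- function(a, b) if (is.null(a)) b else a
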