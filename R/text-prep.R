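#' Clean raw microblog text
#'
#' Strips the markup that dominates microblog noise before segmentation:
#' web links, user mentions (`@name`), hashtag markup (`#topic#` and
#' trailing `#tag`), and emoji / pictographic codepoints. Whitespace is
#' collapsed and trimmed. The function is idempotent and returns `""` for
#' empty input.
#'
#' @param raw character vector of raw post texts.
#' @return character vector of cleaned texts.
#' @export
clean_text <- function(raw) {
  if (length(raw) == 0) return(character(0))
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("@[^[:space:]#@]+", " ", x, perl = TRUE)
  x <- gsub("#[^#]*#", " ", x, perl = TRUE)              # paired hashtag markup
  x <- gsub("#[^[:space:]#]+", " ", x, perl = TRUE)      # bare trailing hashtags
  # emoji: pictographs, emoticons, transport, supplemental symbols, dingbats,
  # misc symbols, plus variation selectors and zero-width joiners
  x <- gsub("[\U0001F000-\U0001FAFF\U00002600-\U000027BF\U0001F1E6-\U0001F1FF\UFE0E\UFE0F\U200D]",
            "", x, perl = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Tokenize cleaned text
#'
#' Splits cleaned text into an ordered token sequence. The default
#' segmenter lower-cases and splits on whitespace and punctuation, which is
#' adequate for space-delimited text; for languages without word
#' boundaries a dictionary-based segmenter can be injected via `segmenter`
#' without changing any downstream contract (it must map one string to a
#' character vector of tokens).
#'
#' @param cleaned a single cleaned string.
#' @param segmenter function(string) -> character vector of tokens.
#' @return character vector of tokens (empty for empty input).
#' @export
tokenize <- function(cleaned, segmenter = default_segmenter) {
  stopifnot(length(cleaned) == 1)
  if (is.na(cleaned) || !nzchar(trimws(cleaned))) return(character(0))
  segmenter(cleaned)
}

#' @rdname tokenize
#' @export
default_segmenter <- function(x) {
  toks <- strsplit(tolower(trimws(x)), "[[:space:][:punct:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Read a stop-word list
#'
#' Plain text, UTF-8, one token per line; blank lines are ignored.
#'
#' @param path file path.
#' @param source_name label recorded with the list.
#' @return a `stopword_list`: list with `words` (character) and
#'   `source_name`.
#' @export
read_stopwords <- function(path, source_name = basename(path)) {
  if (!file.exists(path)) stop("stop-word list not found: ", path)
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- unique(trimws(words))
  words <- words[nzchar(words)]
  structure(list(words = words, source_name = source_name), class = "stopword_list")
}

#' Remove stop words from a token sequence
#'
#' Order-preserving removal of every token present in the stop list. An
#' empty stop list disables filtering and returns the input unchanged.
#'
#' @param tokens character vector of tokens.
#' @param stops a `stopword_list` from [read_stopwords()], or a plain
#'   character vector of stop words.
#' @return the filtered token sequence (a subsequence of the input).
#' @export
filter_stopwords <- function(tokens, stops) {
  words <- if (inherits(stops, "stopword_list")) stops$words else as.character(stops)
  if (length(words) == 0) return(tokens)
  tokens[!(tokens %in% words)]
}

#' Preprocess a corpus of microblog records
#'
#' Applies [clean_text()], [tokenize()] and [filter_stopwords()] to every
#' record that carries raw `text`; records already carrying `tokens` are
#' stop-word filtered only.
#'
#' @param corpus tibble of microblog records (columns `id`, `region`,
#'   `timestamp`, and `text` and/or `tokens`).
#' @param stops stop list as in [filter_stopwords()]; `character(0)`
#'   disables filtering.
#' @param segmenter tokenizer passed to [tokenize()].
#' @return the corpus with a `tokens` list-column of filtered tokens.
#' @export
preprocess_corpus <- function(corpus, stops = character(0), segmenter = default_segmenter) {
  if (!"tokens" %in% names(corpus)) corpus$tokens <- vector("list", nrow(corpus))
  has_toks <- !vapply(corpus$tokens, is.null, logical(1))
  if ("text" %in% names(corpus)) {
    idx <- which(!has_toks)
    if (length(idx) > 0) {
      cleaned <- clean_text(corpus$text[idx])
      corpus$tokens[idx] <- lapply(cleaned, tokenize, segmenter = segmenter)
    }
  } else if (!all(has_toks)) {
    stop("records without tokens need a 'text' column")
  }
  corpus$tokens <- lapply(corpus$tokens, filter_stopwords, stops = stops)
  corpus
}
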