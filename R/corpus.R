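#' Tokenized corpus
#'
#' A corpus is a list of sentences, each a character vector of tokens.
#' Sentences are the unit of expression for subject-action language
#' patterns: no co-occurrence window ever crosses a sentence boundary.
#'
#' @param sentences list of non-empty character vectors of non-empty tokens.
#' @param source provenance string, a file path or `"synthetic"`.
#' @return An object of class `nlelp_corpus`.
#' @export
nlelp_corpus <- function(sentences, source = "synthetic") {
  stopifnot(is.list(sentences))
  keep <- lengths(sentences) > 0L
  sentences <- sentences[keep]
  if (length(sentences) == 0L) stop("empty corpus: no non-empty sentences")
  ok <- vapply(sentences, function(s) is.character(s) && all(nzchar(s)), logical(1))
  if (!all(ok)) stop("sentences must be character vectors of non-empty tokens")
  structure(list(sentences = sentences, source = source),
            class = "nlelp_corpus")
}

#' @export
print.nlelp_corpus <- function(x, ...) {
  cat(sprintf("<nlelp_corpus> %d sentences, %d tokens (source: %s)\n",
              length(x$sentences), sum(lengths(x$sentences)), x$source))
  invisible(x)
}

#' @export
length.nlelp_corpus <- function(x) length(x$sentences)

#' Vocabulary over a corpus
#'
#' Bijective token/id mapping with corpus frequencies. Ids are contiguous
#' integers `1..V`, assigned in decreasing frequency order (ties broken by
#' first appearance in the corpus). Tokens with corpus frequency below
#' `min_count` are excluded; they remain in the corpus sentences and are
#' treated as unknown (they occupy window positions but never contribute
#' to matrices or vectors).
#'
#' @param corpus an [nlelp_corpus()].
#' @param min_count integer frequency floor (>= 1).
#' @return An object of class `nlelp_vocab` with elements `tokens`
#'   (character), `frequency` (integer, parallel to `tokens`) and
#'   `min_count`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(inherits(corpus, "nlelp_corpus"))
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  toks <- unlist(corpus$sentences, use.names = FALSE)
  first_seen <- match(unique(toks), toks)
  uniq <- unique(toks)
  freq <- tabulate(match(toks, uniq))
  ord <- order(-freq, first_seen)
  uniq <- uniq[ord]
  freq <- freq[ord]
  keep <- freq >= min_count
  if (!any(keep)) stop("min_count leaves an empty vocabulary")
  structure(list(tokens = uniq[keep],
                 frequency = as.integer(freq[keep]),
                 min_count = min_count),
            class = "nlelp_vocab")
}

#' @export
print.nlelp_vocab <- function(x, ...) {
  cat(sprintf("<nlelp_vocab> %d tokens (min_count = %d)\n",
              length(x$tokens), x$min_count))
  invisible(x)
}

#' @export
length.nlelp_vocab <- function(x) length(x$tokens)

#' Token to id lookup
#'
#' @param vocab an `nlelp_vocab`.
#' @param tokens character vector.
#' @return Integer ids; `NA` for unknown (out-of-vocabulary) tokens.
#' @export
vocab_id <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "nlelp_vocab"))
  match(tokens, vocab$tokens)
}

#' Id to token lookup
#'
#' @param vocab an `nlelp_vocab`.
#' @param ids integer ids in `1..length(vocab)`.
#' @return Character tokens.
#' @export
vocab_token <- function(vocab, ids) {
  stopifnot(inherits(vocab, "nlelp_vocab"))
  if (any(ids < 1L | ids > length(vocab$tokens), na.rm = TRUE))
    stop("id out of range")
  vocab$tokens[ids]
}

#' Load a tokenized corpus from a text file
#'
#' Reads a UTF-8 plain-text corpus, one sentence per line with
#' whitespace-delimited tokens, and builds its vocabulary.
#'
#' @param path file path.
#' @param min_count frequency floor passed to [build_vocab()].
#' @return A list with elements `corpus` ([nlelp_corpus()]) and `vocab`
#'   ([build_vocab()]).
#' @export
load_corpus <- function(path, min_count = 1L) {
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus: ", path)
  sentences <- strsplit(trimws(lines), "[[:space:]]+")
  corpus <- nlelp_corpus(sentences, source = path)
  list(corpus = corpus, vocab = build_vocab(corpus, min_count))
}

#' Write a corpus to a text file
#'
#' One sentence per line, single-space token delimiter, UTF-8.
#'
#' @param corpus an [nlelp_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "nlelp_corpus"))
  lines <- vapply(corpus$sentences, paste, character(1), collapse = " ")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Enumerate sliding windows of preceding context
#'
#' For every token position in every sentence, emits the target token and
#' its up to `n` immediately preceding tokens in the same sentence
#' (nearest last). Windows never cross sentence boundaries, so the context
#' is truncated at the sentence start. One window is produced per token
#' position; the total window count equals the corpus token count.
#'
#' @param corpus an [nlelp_corpus()].
#' @param n window size (number of preceding tokens), >= 1.
#' @return A list of `list(target =, context =)` records; `context` is a
#'   character vector of length `0..n`, ordered nearest-last.
#' @export
corpus_windows <- function(corpus, n) {
  stopifnot(inherits(corpus, "nlelp_corpus"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("window size n must be >= 1")
  out <- vector("list", sum(lengths(corpus$sentences)))
  k <- 0L
  for (sent in corpus$sentences) {
    for (t in seq_along(sent)) {
      lo <- max(1L, t - n)
      k <- k + 1L
      out[[k]] <- list(target = sent[[t]],
                       context = if (t > 1L) sent[lo:(t - 1L)] else character(0))
    }
  }
  out
}
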