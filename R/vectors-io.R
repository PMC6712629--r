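#' Word vector table
#'
#' Dense per-word vectors: one row per vocabulary word. These are the
#' V(.) looked up by the analogy engines, whether trained embeddings,
#' HAL-VEC rows or vectors loaded from disk.
#'
#' @param vectors numeric matrix, rows named by token.
#' @param provenance one of "cbow", "sg", "hal", "loaded".
#' @return An object of class `word_vectors`.
#' @export
word_vectors <- function(vectors, provenance = "loaded") {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors))) stop("vectors must have token rownames")
  if (anyDuplicated(rownames(vectors))) stop("duplicate tokens in vector table")
  if (ncol(vectors) < 1L) stop("dimension must be positive")
  if (!all(is.finite(vectors))) stop("non-finite entries in vector table")
  provenance <- match.arg(provenance, c("cbow", "sg", "hal", "loaded"))
  structure(list(vectors = vectors, dim = ncol(vectors),
                 provenance = provenance),
            class = "word_vectors")
}

#' @export
print.word_vectors <- function(x, ...) {
  cat(sprintf("<word_vectors> %d words x %d dims (%s)\n",
              nrow(x$vectors), x$dim, x$provenance))
  invisible(x)
}

#' Look up word vectors
#'
#' @param wv a [word_vectors()] table.
#' @param tokens character vector of tokens, all of which must be present.
#' @return Numeric matrix with one row per requested token.
#' @export
get_vectors <- function(wv, tokens) {
  stopifnot(inherits(wv, "word_vectors"))
  i <- match(tokens, rownames(wv$vectors))
  if (anyNA(i))
    stop("word not in vector table: ",
         paste(tokens[is.na(i)], collapse = ", "))
  wv$vectors[i, , drop = FALSE]
}

#' Write word vectors in word2vec text format
#'
#' First line `"<count> <dim>"`, then one line per word: the token
#' followed by `dim` space-separated floats. Token order is preserved.
#'
#' @param wv a [word_vectors()] table.
#' @param path output path.
#' @param digits significant digits for the floats (default 8, round-trips
#'   well within 1e-6).
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(wv, path, digits = 8L) {
  stopifnot(inherits(wv, "word_vectors"))
  m <- wv$vectors
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con, useBytes = TRUE)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = digits, format = "g")),
          collapse = " ")
  }, character(1))
  writeLines(body, con, useBytes = TRUE)
  invisible(path)
}

#' Read word vectors in word2vec text format
#'
#' @param path input path; first line must be `"<count> <dim>"`.
#' @return A [word_vectors()] table with provenance `"loaded"`.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) stop("cannot read vectors: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("format error in ", path, " line 1: empty file")
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  count <- suppressWarnings(as.integer(hdr[1L]))
  dim <- suppressWarnings(as.integer(hdr[2L]))
  if (length(hdr) != 2L || is.na(count) || is.na(dim) || count < 1L || dim < 1L)
    stop("format error in ", path, " line 1: expected '<count> <dim>' header")
  if (length(lines) - 1L != count)
    stop("format error in ", path, ": header declares ", count,
         " rows but file has ", length(lines) - 1L)
  toks <- character(count)
  m <- matrix(NA_real_, count, dim)
  for (i in seq_len(count)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != dim + 1L)
      stop("format error in ", path, " line ", i + 1L, ": expected ",
           dim + 1L, " fields, found ", length(parts))
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals))
      stop("format error in ", path, " line ", i + 1L, ": non-numeric value")
    toks[i] <- parts[1L]
    m[i, ] <- vals
  }
  rownames(m) <- toks
  word_vectors(m, provenance = "loaded")
}
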