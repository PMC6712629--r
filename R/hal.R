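#' Build a hyperspace-analog-to-language co-occurrence matrix
#'
#' Slides a window of the `n` preceding tokens over every sentence. For a
#' target token and an in-vocabulary token at distance `d` (1 = adjacent)
#' the cell (target, context) accumulates weight `n - d + 1`: the
#' adjacent word receives weight `n`, the furthest word in the window
#' weight 1. Windows never cross sentence boundaries. Out-of-vocabulary
#' tokens occupy window positions (distances are preserved) but never
#' contribute weight, and targets outside the vocabulary are skipped.
#'
#' @param corpus an [nlelp_corpus()].
#' @param vocab an [build_vocab()] vocabulary.
#' @param n window size (number of preceding words), >= 1.
#' @return An object of class `hal_matrix`: list with `weights` (dense
#'   vocab x vocab matrix, row = target word, column = preceding-context
#'   word) and `window_n`.
#' @export
build_hal <- function(corpus, vocab, n) {
  stopifnot(inherits(corpus, "nlelp_corpus"), inherits(vocab, "nlelp_vocab"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("window size n must be >= 1")
  V <- length(vocab$tokens)
  if (V == 0L) stop("empty vocabulary")

  ids <- unlist(lapply(corpus$sentences, vocab_id, vocab = vocab),
                use.names = FALSE)
  sent <- rep.int(seq_along(corpus$sentences), lengths(corpus$sentences))
  N <- length(ids)
  acc <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(V, V))
  for (d in seq_len(min(n, N - 1L))) {
    tgt_pos <- (d + 1L):N
    ctx_pos <- tgt_pos - d
    ok <- sent[tgt_pos] == sent[ctx_pos] &
      !is.na(ids[tgt_pos]) & !is.na(ids[ctx_pos])
    if (!any(ok)) next
    acc <- acc + Matrix::sparseMatrix(i = ids[tgt_pos][ok],
                                      j = ids[ctx_pos][ok],
                                      x = rep.int(n - d + 1, sum(ok)),
                                      dims = c(V, V))
  }
  weights <- as.matrix(acc)
  dimnames(weights) <- list(vocab$tokens, vocab$tokens)
  structure(list(weights = weights, window_n = n), class = "hal_matrix")
}

#' @export
print.hal_matrix <- function(x, ...) {
  cat(sprintf("<hal_matrix> %d x %d, window %d, total mass %g\n",
              nrow(x$weights), ncol(x$weights), x$window_n, sum(x$weights)))
  invisible(x)
}

#' Extract word vectors from a representation
#'
#' Rows of the HAL matrix serve as HAL-VEC word vectors (dimension =
#' vocabulary size); embedding tables pass through unchanged.
#'
#' @param x an object holding per-word vectors.
#' @param ... unused.
#' @return A [word_vectors()] table.
#' @export
as_word_vectors <- function(x, ...) UseMethod("as_word_vectors")

#' @export
as_word_vectors.hal_matrix <- function(x, ...) {
  word_vectors(x$weights, provenance = "hal")
}

#' @export
as_word_vectors.word_vectors <- function(x, ...) x

#' Write a sparse co-occurrence matrix as triplet TSV
#'
#' One line per non-zero cell: row token, column token, value. A sidecar
#' file `<path>.meta` records the window size and a vocabulary hash so a
#' reload can be checked against the representation it came from.
#'
#' @param x an `hal_matrix` or `ppmi_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "hal_matrix")) {
    m <- x$weights
    window <- x$window_n
    kind <- "hal"
    idx <- which(m != 0, arr.ind = TRUE)
    vals <- m[idx]
    toks_r <- rownames(m)[idx[, 1L]]
    toks_c <- colnames(m)[idx[, 2L]]
    vocab_tokens <- rownames(m)
  } else if (inherits(x, "ppmi_matrix")) {
    trip <- Matrix::summary(x$values)
    window <- x$window_w
    kind <- "ppmi"
    toks_r <- rownames(x$values)[trip$i]
    toks_c <- colnames(x$values)[trip$j]
    vals <- trip$x
    vocab_tokens <- rownames(x$values)
  } else stop("unsupported matrix type")
  ord <- order(toks_r, toks_c)
  df <- data.frame(row = toks_r[ord], col = toks_c[ord], value = vals[ord],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  meta <- c(paste0("kind\t", kind),
            paste0("window\t", window),
            paste0("vocab_hash\t", vocab_hash(vocab_tokens)),
            paste0("vocab\t", paste(vocab_tokens, collapse = " ")))
  writeLines(meta, paste0(path, ".meta"), useBytes = TRUE)
  invisible(path)
}

vocab_hash <- function(tokens) {
  # order-sensitive polynomial rolling hash; stable across platforms
  h <- 0
  for (byte in utf8ToInt(paste(tokens, collapse = "\x1f")))
    h <- (h * 31 + byte) %% 2147483647
  format(h)
}

#' Read a sparse co-occurrence matrix from triplet TSV
#'
#' @param path TSV written by [write_matrix_tsv()] (its `.meta` sidecar
#'   must be present).
#' @return An `hal_matrix` or `ppmi_matrix`, per the sidecar `kind`.
#' @export
read_matrix_tsv <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("cannot read matrix (need TSV and .meta sidecar): ", path)
  meta_lines <- readLines(meta_path, encoding = "UTF-8")
  meta <- strsplit(meta_lines, "\t", fixed = TRUE)
  keys <- vapply(meta, `[`, character(1), 1L)
  vals <- vapply(meta, function(x) paste(x[-1L], collapse = "\t"), character(1))
  meta <- setNames(vals, keys)
  tokens <- strsplit(meta[["vocab"]], " ", fixed = TRUE)[[1L]]
  V <- length(tokens)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("row", "col", "value"),
                   fileEncoding = "UTF-8")
  i <- match(df$row, tokens)
  j <- match(df$col, tokens)
  if (anyNA(i) || anyNA(j))
    stop("format error in ", path, ": token outside sidecar vocabulary at line ",
         which(is.na(i) | is.na(j))[1L])
  if (meta[["kind"]] == "hal") {
    m <- matrix(0, V, V, dimnames = list(tokens, tokens))
    m[cbind(i, j)] <- df$value
    structure(list(weights = m, window_n = as.integer(meta[["window"]])),
              class = "hal_matrix")
  } else {
    sm <- Matrix::sparseMatrix(i = i, j = j, x = df$value, dims = c(V, V),
                               dimnames = list(tokens, tokens))
    structure(list(values = sm, window_w = as.integer(meta[["window"]]),
                   total_pairs = NA_real_),
              class = "ppmi_matrix")
  }
}
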