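#' Build a positive pointwise mutual information matrix
#'
#' Counts co-occurrences of in-vocabulary tokens within distance `w`
#' inside a sentence: every ordered position pair (i, j) with
#' 0 < |i - j| <= w contributes one count to (token_i, token_j), so the
#' count matrix is symmetric by construction. With D the total count,
#' p(x, y) = count(x, y) / D and p(x) = row-marginal(x) / D; then
#' PMI(x, y) = log(p(x, y) / (p(x) p(y))) (natural log) and
#' PPMI = max(PMI, 0). Pairs that never co-occur have PPMI 0 and are not
#' stored; only strictly positive scores are kept in the sparse matrix.
#'
#' @param corpus an [nlelp_corpus()].
#' @param vocab a [build_vocab()] vocabulary.
#' @param w co-occurrence window size, >= 1.
#' @return An object of class `ppmi_matrix`: list with `values` (sparse
#'   symmetric vocab x vocab matrix of positive PPMI scores), `window_w`
#'   and `total_pairs` (D).
#' @export
build_ppmi <- function(corpus, vocab, w) {
  stopifnot(inherits(corpus, "nlelp_corpus"), inherits(vocab, "nlelp_vocab"))
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("window size w must be >= 1")
  V <- length(vocab$tokens)

  ids <- unlist(lapply(corpus$sentences, vocab_id, vocab = vocab),
                use.names = FALSE)
  sent <- rep.int(seq_along(corpus$sentences), lengths(corpus$sentences))
  N <- length(ids)
  counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(V, V))
  for (d in seq_len(min(w, N - 1L))) {
    a_pos <- (d + 1L):N
    b_pos <- a_pos - d
    ok <- sent[a_pos] == sent[b_pos] & !is.na(ids[a_pos]) & !is.na(ids[b_pos])
    if (!any(ok)) next
    a <- ids[a_pos][ok]
    b <- ids[b_pos][ok]
    # both directions: ordered-pair enumeration keeps marginals consistent
    counts <- counts +
      Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1,
                           dims = c(V, V))
  }
  D <- sum(counts)
  if (D == 0) stop("no co-occurring pairs in corpus (total pair count 0)")
  marg <- Matrix::rowSums(counts)
  trip <- Matrix::summary(counts)
  pmi <- log(trip$x * D / (marg[trip$i] * marg[trip$j]))
  pos <- pmi > 0
  values <- Matrix::sparseMatrix(i = trip$i[pos], j = trip$j[pos],
                                 x = pmi[pos], dims = c(V, V),
                                 dimnames = list(vocab$tokens, vocab$tokens))
  structure(list(values = values, window_w = w, total_pairs = D),
            class = "ppmi_matrix")
}

#' @export
print.ppmi_matrix <- function(x, ...) {
  cat(sprintf("<ppmi_matrix> %d x %d, window %d, %d positive cells, D = %s\n",
              nrow(x$values), ncol(x$values), x$window_w,
              length(x$values@x), format(x$total_pairs)))
  invisible(x)
}

#' Look up PPMI scores
#'
#' @param ppmi a `ppmi_matrix`.
#' @param x,y token vectors (recycled to common length).
#' @return Numeric PPMI scores; 0 for never-co-occurring or unknown pairs.
#' @export
ppmi_score <- function(ppmi, x, y) {
  stopifnot(inherits(ppmi, "ppmi_matrix"))
  toks <- rownames(ppmi$values)
  i <- match(x, toks)
  j <- match(y, toks)
  n <- max(length(i), length(j))
  i <- rep_len(i, n)
  j <- rep_len(j, n)
  out <- numeric(n)
  ok <- !is.na(i) & !is.na(j)
  if (any(ok)) out[ok] <- ppmi$values[cbind(i[ok], j[ok])]
  out
}
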