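#' Analogy target vector
#'
#' The vector arithmetic at the heart of analogical inference: for a
#' query <alpha:beta>::<alpha_star:?>, the target action vector is
#' `V(beta) - V(alpha) + V(alpha_star)` (the lambda combination also used
#' by the HAL information-inference score).
#'
#' @param wv a [word_vectors()] table.
#' @param alpha,beta,alpha_star query tokens, all in the vocabulary.
#' @return A numeric d-vector.
#' @export
analogy_target <- function(wv, alpha, beta, alpha_star) {
  v <- get_vectors(wv, c(alpha, beta, alpha_star))
  v[2L, ] - v[1L, ] + v[3L, ]
}

cosine_to <- function(m, v) {
  # cosine of each row of m against v; zero vectors score 0 with a warning
  vn <- sqrt(sum(v^2))
  rn <- sqrt(rowSums(m^2))
  if (vn == 0 || any(rn == 0)) {
    warning("zero vector in cosine similarity; score set to 0")
    if (vn == 0) return(rep(0, nrow(m)))
  }
  out <- unname(as.vector(m %*% v) / (rn * vn))
  out[rn == 0] <- 0
  out
}

as_query <- function(query) {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query <- as.list(query[1L, ])
  }
  stopifnot(all(c("alpha", "beta", "alpha_star") %in% names(query)))
  query
}

#' Additive cosine analogy score
#'
#' Cosine similarity of the candidate vector against the analogy target
#' `V(beta) - V(alpha) + V(alpha_star)` (3CosAdd).
#'
#' @param wv a [word_vectors()] table.
#' @param query list or one-row data.frame with `alpha`, `beta`,
#'   `alpha_star`.
#' @param candidate candidate token.
#' @return Score in `[-1, 1]`; 0 (with a warning) for zero vectors.
#' @export
score_cosine <- function(wv, query, candidate) {
  q <- as_query(query)
  target <- analogy_target(wv, q$alpha, q$beta, q$alpha_star)
  cosine_to(get_vectors(wv, candidate), target)
}

#' Multiplicative cosine analogy score
#'
#' 3CosMul: `cos(c, beta) * cos(c, alpha_star) / (cos(c, alpha) + eps)`,
#' with a small eps preventing division by zero. Cosines are used as-is
#' (no shift into `[0, 1]`), so negative cosines can yield negative
#' scores.
#'
#' @inheritParams score_cosine
#' @param epsilon denominator guard, default 0.001.
#' @return Numeric score.
#' @export
score_cosmul <- function(wv, query, candidate, epsilon = 0.001) {
  q <- as_query(query)
  m <- get_vectors(wv, candidate)
  cb <- cosine_to(m, get_vectors(wv, q$beta)[1L, ])
  cs <- cosine_to(m, get_vectors(wv, q$alpha_star)[1L, ])
  ca <- cosine_to(m, get_vectors(wv, q$alpha)[1L, ])
  cb * cs / (ca + epsilon)
}

quality_properties <- function(v) {
  # indices whose weight exceeds the vector's mean component value
  which(v > mean(v))
}

#' HAL information-inference score
#'
#' Compares a candidate vector against the analogy combination
#' `lambda = V(beta) - V(alpha) + V(alpha_star)` using only "quality
#' property" dimensions: those whose weight exceeds the vector's mean
#' component value. The score sums the candidate's weights over the
#' shared quality properties and normalizes by the total quality-property
#' mass of lambda. The mean threshold is applied to lambda exactly as to
#' any vector, even when its mean is negative.
#'
#' @inheritParams score_cosine
#' @return Numeric score; 0 (with a warning) when lambda has no quality
#'   properties or non-positive quality mass.
#' @export
score_halinf <- function(wv, query, candidate) {
  q <- as_query(query)
  lambda <- analogy_target(wv, q$alpha, q$beta, q$alpha_star)
  qp_l <- quality_properties(lambda)
  denom <- sum(lambda[qp_l])
  if (length(qp_l) == 0L || denom <= 0) {
    warning("lambda has no usable quality properties; score set to 0")
    return(rep(0, length(candidate)))
  }
  m <- get_vectors(wv, candidate)
  ml <- m[, qp_l, drop = FALSE]
  unname(rowSums(ml * (ml > rowMeans(m)))) / denom
}

#' PPMI induction score
#'
#' Single-subject induction: the score of a candidate action for a query
#' is simply `PPMI(alpha_star, candidate)`; the query's alpha and beta
#' play no role.
#'
#' @param ppmi a [build_ppmi()] matrix.
#' @param subject subject token (the query's alpha_star).
#' @param candidate candidate token(s).
#' @return Non-negative score; 0 (with a warning) for unknown subjects.
#' @export
score_ppmi <- function(ppmi, subject, candidate) {
  stopifnot(inherits(ppmi, "ppmi_matrix"))
  if (!(subject %in% rownames(ppmi$values))) {
    warning("subject not in vocabulary: ", subject, "; scores set to 0")
    return(rep(0, length(candidate)))
  }
  ppmi_score(ppmi, subject, candidate)
}

#' Part-of-speech candidate filter
#'
#' Language patterns are <noun:verb> pairs, so candidate actions are
#' filtered by part of speech: a token passes when the lexicon tags it
#' with one of the allowed tags. Tokens absent from the lexicon never
#' pass.
#'
#' @param pos_lexicon named character vector token -> tag, or a
#'   data.frame with columns `token` and `pos`.
#' @param allowed allowed tags for candidate actions (default "verb").
#' @return An object of class `candidate_filter`.
#' @export
candidate_filter <- function(pos_lexicon, allowed = "verb") {
  if (is.data.frame(pos_lexicon)) {
    stopifnot(all(c("token", "pos") %in% names(pos_lexicon)))
    pos_lexicon <- setNames(as.character(pos_lexicon$pos),
                            pos_lexicon$token)
  }
  stopifnot(is.character(pos_lexicon), !is.null(names(pos_lexicon)))
  structure(list(lexicon = pos_lexicon, allowed = as.character(allowed)),
            class = "candidate_filter")
}

#' Apply a candidate filter to tokens
#'
#' @param filter a [candidate_filter()], or `NULL` to pass everything.
#' @param tokens character vector.
#' @return Logical vector, `TRUE` where the token passes.
#' @export
filter_tokens <- function(filter, tokens) {
  if (is.null(filter)) return(rep(TRUE, length(tokens)))
  stopifnot(inherits(filter, "candidate_filter"))
  tags <- filter$lexicon[tokens]
  !is.na(tags) & tags %in% filter$allowed
}

#' Read a part-of-speech lexicon from TSV
#'
#' Two columns: token, tag (noun / verb / other).
#'
#' @param path TSV path.
#' @return data.frame with columns `token` and `pos`.
#' @export
read_pos_lexicon <- function(path) {
  if (!file.exists(path)) stop("cannot read POS lexicon: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("format error in ", path, ": need 2 tab columns")
  data.frame(token = df[[1L]], pos = df[[2L]], stringsAsFactors = FALSE)
}

engine_scores <- function(engine, representation, q, candidates) {
  switch(engine,
    cosine = {
      target <- analogy_target(representation, q$alpha, q$beta, q$alpha_star)
      cosine_to(get_vectors(representation, candidates), target)
    },
    cosmul = score_cosmul(representation, q, candidates),
    halinf = score_halinf(representation, q, candidates),
    ppmi = score_ppmi(representation, q$alpha_star, candidates),
    stop("unknown engine: ", engine))
}

representation_tokens <- function(representation) {
  if (inherits(representation, "word_vectors")) rownames(representation$vectors)
  else if (inherits(representation, "ppmi_matrix")) rownames(representation$values)
  else stop("unsupported representation type")
}

check_engine_compat <- function(engine, representation) {
  if (engine == "ppmi") {
    if (!inherits(representation, "ppmi_matrix"))
      stop("engine 'ppmi' requires a ppmi_matrix representation")
  } else {
    if (!inherits(representation, "word_vectors"))
      stop("engine '", engine, "' requires a word_vectors representation")
  }
}

#' Rank candidate actions for an analogy query
#'
#' Scores every vocabulary token that passes the candidate filter,
#' excluding the query words alpha, beta and alpha_star, and returns the
#' candidates sorted by score (descending; ties broken by ascending token
#' id, i.e. vocabulary order), truncated to `top_k`.
#'
#' @param engine one of "cosine", "cosmul", "halinf", "ppmi".
#' @param representation a [word_vectors()] table (cosine/cosmul/halinf)
#'   or [build_ppmi()] matrix (ppmi).
#' @param query list or one-row data.frame with `alpha`, `beta`,
#'   `alpha_star`.
#' @param filter a [candidate_filter()] or `NULL`.
#' @param top_k ranking depth (default 100).
#' @return An object of class `ranked_result`: list with `query`,
#'   `engine`, `candidates` (character) and `scores` (non-increasing).
#' @export
rank_candidates <- function(engine, representation, query, filter = NULL,
                            top_k = 100L) {
  engine <- match.arg(engine, c("cosine", "cosmul", "halinf", "ppmi"))
  check_engine_compat(engine, representation)
  q <- as_query(query)
  toks <- representation_tokens(representation)
  keep <- filter_tokens(filter, toks) &
    !(toks %in% c(q$alpha, q$beta, q$alpha_star))
  candidates <- toks[keep]
  if (length(candidates) == 0L) {
    warning("no candidates remain after filtering")
    return(structure(list(query = q, engine = engine,
                          candidates = character(0), scores = numeric(0)),
                     class = "ranked_result"))
  }
  scores <- engine_scores(engine, representation, q, candidates)
  ord <- order(-scores, seq_along(candidates))
  ord <- head(ord, top_k)
  structure(list(query = q, engine = engine,
                 candidates = candidates[ord], scores = scores[ord]),
            class = "ranked_result")
}

#' @export
print.ranked_result <- function(x, ...) {
  cat(sprintf("<ranked_result> engine %s, <%s:%s>::<%s:?>, %d candidates\n",
              x$engine, x$query$alpha, x$query$beta, x$query$alpha_star,
              length(x$candidates)))
  if (length(x$candidates)) {
    show <- head(seq_along(x$candidates), 5L)
    cat(paste(sprintf("  %d. %s (%.4f)", show, x$candidates[show],
                      x$scores[show]), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write ranked results to TSV
#'
#' Columns: query id, rank, candidate, score, engine.
#'
#' @param results list of `ranked_result` objects.
#' @param path output path.
#' @param query_ids optional ids parallel to `results` (default seq).
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(results, path, query_ids = seq_along(results)) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (length(r$candidates) == 0L) return(NULL)
    data.frame(query_id = query_ids[i], rank = seq_along(r$candidates),
               candidate = r$candidates, score = r$scores, engine = r$engine,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(query_id = integer(0), rank = integer(0),
                     candidate = character(0), score = numeric(0),
                     engine = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
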