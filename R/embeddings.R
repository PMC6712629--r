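#' Embedding training configuration
#'
#' Hyper-parameters for the shallow log-linear embedding trainers. CBOW
#' predicts the current word from the mean of its context vectors;
#' skip-gram uses the current word as input and predicts each context
#' word. Both are trained with negative sampling against a unigram^0.75
#' noise distribution, with a linearly decaying learning rate, and return
#' the input-side vectors.
#'
#' @param architecture "cbow" or "sg".
#' @param dim embedding dimension (default 300, inside the usual
#'   100-600 sweep range).
#' @param window symmetric context window size.
#' @param negative negative samples per positive example, >= 1.
#' @param epochs training epochs, >= 1.
#' @param alpha initial learning rate.
#' @param seed integer seed; training is bit-deterministic under it.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(architecture = c("cbow", "sg"), dim = 300L,
                             window = 5L, negative = 5L, epochs = 5L,
                             alpha = 0.025, seed = 1L) {
  architecture <- match.arg(architecture)
  cfg <- list(architecture = architecture, dim = as.integer(dim),
              window = as.integer(window), negative = as.integer(negative),
              epochs = as.integer(epochs), alpha = as.numeric(alpha),
              seed = as.integer(seed))
  if (cfg$dim < 1L) stop("dim must be >= 1")
  if (cfg$window < 1L) stop("window must be >= 1")
  if (cfg$negative < 1L) stop("negative must be >= 1")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (!(cfg$alpha > 0)) stop("alpha must be > 0")
  structure(cfg, class = "embedding_config")
}

#' Train CBOW or skip-gram word embeddings
#'
#' Runs the negative-sampling trainer over the corpus and returns the
#' input-side word vectors. Out-of-vocabulary tokens occupy sentence
#' positions but are never used as centers, contexts or negatives.
#'
#' @param corpus an [nlelp_corpus()].
#' @param vocab a [build_vocab()] vocabulary.
#' @param cfg an [embedding_config()].
#' @return A [word_vectors()] table with provenance `"cbow"` or `"sg"`.
#' @export
train_embeddings <- function(corpus, vocab, cfg = embedding_config()) {
  stopifnot(inherits(corpus, "nlelp_corpus"), inherits(vocab, "nlelp_vocab"),
            inherits(cfg, "embedding_config"))
  V <- length(vocab$tokens)
  if (V < 2L)
    stop("vocabulary too small for negative sampling (need >= 2 words)")
  sent_ids <- lapply(corpus$sentences, vocab_id, vocab = vocab)
  noise <- vocab$frequency^0.75
  log_debug("training ", cfg$architecture, " d=", cfg$dim,
            " epochs=", cfg$epochs, " on ", length(sent_ids), " sentences")
  m <- .sgns_train(sent_ids, V, noise, cfg$architecture == "cbow",
                   cfg$dim, cfg$window, cfg$negative, cfg$epochs,
                   cfg$alpha, cfg$seed)
  rownames(m) <- vocab$tokens
  word_vectors(m, provenance = cfg$architecture)
}

#' Mean of context vectors
#'
#' The hidden vector of the CBOW architecture: the component-wise
#' arithmetic mean of the context word vectors.
#'
#' @param vectors a list of equal-length numeric vectors, or a numeric
#'   matrix with one vector per row.
#' @return A numeric vector.
#' @export
context_mean <- function(vectors) {
  if (is.matrix(vectors)) {
    if (nrow(vectors) == 0L) stop("empty context")
    return(colMeans(vectors))
  }
  if (!is.list(vectors) || length(vectors) == 0L) stop("empty context")
  d <- unique(lengths(vectors))
  if (length(d) != 1L) stop("context vectors have differing dimensions")
  colMeans(do.call(rbind, vectors))
}
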