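# Shared fixtures. The benchmark world (the package's default synthetic
# study conditions) is expensive to build and train on, so it is cached
# for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

# Benchmark world: default generator spec (10 subjects in 5 categories,
# 20 actions, density 0.5, 5000 sentences) with trained CBOW vectors and
# a PPMI matrix, plus its query partition.
benchmark_fixture <- function() {
  if (!is.null(.fixture_cache$benchmark)) return(.fixture_cache$benchmark)
  world <- generate_synthetic_world(synthetic_world_spec(seed = 1))
  vocab <- build_vocab(world$corpus)
  cbow <- train_embeddings(world$corpus, vocab,
                           embedding_config("cbow", dim = 32L, epochs = 30L,
                                            seed = 101L))
  ppmi <- build_ppmi(world$corpus, vocab, 3L)
  queries <- generate_queries(world$lr)
  partition <- suppressWarnings(
    partition_queries(queries, 0L, 40L, seed = 3L))
  filter <- candidate_filter(world$pos)
  .fixture_cache$benchmark <- list(world = world, vocab = vocab,
                                   cbow = cbow, ppmi = ppmi,
                                   queries = queries, partition = partition,
                                   filter = filter)
  .fixture_cache$benchmark
}

# A small corpus with known token statistics, written to a temp file.
tiny_corpus_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# Random word-vector table over the given tokens.
random_vectors <- function(tokens, d, seed) {
  set.seed(seed)
  m <- matrix(rnorm(length(tokens) * d), nrow = length(tokens),
              dimnames = list(tokens, NULL))
  word_vectors(m, provenance = "loaded")
}

# Random logical-relationship matrix.
random_lr <- function(n_actions, n_subjects, seed, p = 0.5,
                      n_categories = min(5L, n_subjects)) {
  set.seed(seed)
  cells <- matrix(runif(n_actions * n_subjects) < p, n_actions, n_subjects,
                  dimnames = list(sprintf("act%02d", seq_len(n_actions)),
                                  sprintf("sub%02d", seq_len(n_subjects))))
  cats <- setNames(sprintf("cat%d", rep_len(seq_len(n_categories),
                                            n_subjects)),
                   colnames(cells))
  lr_matrix(cells, cats)
}
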