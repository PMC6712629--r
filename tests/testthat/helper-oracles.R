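# Independent brute-force oracles shared across test files. These follow
# the definitions literally (naive loops) and never call the package's
# own accumulation paths.

# HAL: naive double loop over every window position.
hal_oracle <- function(corpus, vocab, n) {
  V <- length(vocab$tokens)
  m <- matrix(0, V, V, dimnames = list(vocab$tokens, vocab$tokens))
  for (sent in corpus$sentences) {
    for (t in seq_along(sent)) {
      for (d in seq_len(min(n, t - 1))) {
        tgt <- sent[t]
        ctx <- sent[t - d]
        if (tgt %in% vocab$tokens && ctx %in% vocab$tokens)
          m[tgt, ctx] <- m[tgt, ctx] + (n - d + 1)
      }
    }
  }
  m
}

# PPMI: enumerate every ordered in-sentence position pair within the
# window and evaluate the PMI definition directly.
ppmi_oracle <- function(corpus, vocab, w) {
  toks <- vocab$tokens
  V <- length(toks)
  counts <- matrix(0, V, V, dimnames = list(toks, toks))
  for (sent in corpus$sentences) {
    for (i in seq_along(sent)) {
      for (j in seq_along(sent)) {
        if (i != j && abs(i - j) <= w &&
            sent[i] %in% toks && sent[j] %in% toks)
          counts[sent[i], sent[j]] <- counts[sent[i], sent[j]] + 1
      }
    }
  }
  D <- sum(counts)
  marg <- rowSums(counts)
  out <- matrix(0, V, V, dimnames = list(toks, toks))
  for (x in toks) for (y in toks) {
    if (counts[x, y] > 0) {
      pmi <- log((counts[x, y] / D) / ((marg[x] / D) * (marg[y] / D)))
      out[x, y] <- max(0, pmi)
    }
  }
  out
}
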