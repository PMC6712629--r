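cosm <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

test_that("the analogy target is the additive vector combination", {
  wv <- word_vectors(matrix(c(1, 0,
                              0, 1,
                              1, 1), nrow = 3, byrow = TRUE,
                            dimnames = list(c("beta", "alpha", "alpha_star"),
                                            NULL)))
  expect_equal(analogy_target(wv, "alpha", "beta", "alpha_star"), c(2, 0))
  # alpha == alpha_star cancels
  expect_equal(analogy_target(wv, "alpha", "beta", "alpha"), c(1, 0))
  rv <- random_vectors(letters[1:4], 5, seed = 3)
  m <- rv$vectors
  expect_equal(analogy_target(rv, "a", "b", "c"),
               m["b", ] - m["a", ] + m["c", ])
  expect_error(analogy_target(rv, "a", "zz", "c"), "zz")
})

test_that("cosine scoring hits the closed-form endpoints", {
  m <- matrix(c(1, 0,
                0, 2,
                3, 0,
                0, -1), nrow = 4, byrow = TRUE,
              dimnames = list(c("b", "a", "cand_par", "cand_orth"), NULL))
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "a")  # target = V(b)
  expect_equal(score_cosine(wv, q, "cand_par"), 1)
  expect_equal(score_cosine(wv, q, "cand_orth"), 0)
})

test_that("cosine and cosmul match their definitional oracles", {
  rv <- random_vectors(c("a", "b", "s", paste0("c", 1:20)), 8, seed = 9)
  m <- rv$vectors
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  target <- m["b", ] - m["a", ] + m["s", ]
  for (cand in paste0("c", 1:20)) {
    expect_equal(score_cosine(rv, q, cand), cosm(m[cand, ], target),
                 tolerance = 1e-9)
    oracle_mul <- cosm(m[cand, ], m["b", ]) * cosm(m[cand, ], m["s", ]) /
      (cosm(m[cand, ], m["a", ]) + 0.001)
    expect_equal(score_cosmul(rv, q, cand), oracle_mul, tolerance = 1e-9)
  }
})

test_that("cosmul follows the multiplicative combination exactly", {
  # cos(c, beta) = 1, cos(c, alpha_star) = 1, cos(c, alpha) = 0
  m <- matrix(c(1, 0,
                1, 0,
                0, 1,
                2, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("b", "s", "a", "cand"), NULL))
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  expect_equal(score_cosmul(wv, q, "cand"), 1000)
  # orthogonal to beta: multiplicative zero regardless of other terms
  m2 <- m
  m2["cand", ] <- c(0, 5)
  expect_equal(score_cosmul(word_vectors(m2), q, "cand"), 0)
})

test_that("zero vectors score zero with a warning", {
  m <- matrix(c(1, 0,
                0, 1,
                1, 1,
                0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("b", "a", "s", "zero"), NULL))
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  expect_warning(sc <- score_cosine(wv, q, "zero"), "zero vector")
  expect_equal(sc, 0)
})

test_that("quality properties are the dimensions above the mean", {
  v <- c(1, 2, 3, 6)
  expect_equal(nlelp:::quality_properties(v), 4L)  # delta = 3, only 6 > 3
  # HAL-INF with an empty quality intersection scores zero
  m <- matrix(c(0, 10, 0, 0,
                0, 0,  0, 0,
                0, 0,  0, 0,
                5, 0,  0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(c("b", "a", "s", "cand"), NULL))
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  # lambda = (0,10,0,0): QP = {2}; cand QP = {1}; empty intersection
  expect_equal(score_halinf(wv, q, "cand"), 0)
})

test_that("HAL-INF matches a literal set-builder oracle", {
  set.seed(14)
  for (rep in 1:25) {
    m <- matrix(runif(6 * 8), nrow = 6,
                dimnames = list(c("a", "b", "s", "c1", "c2", "c3"), NULL))
    wv <- word_vectors(m)
    q <- list(alpha = "a", beta = "b", alpha_star = "s")
    lambda <- m["b", ] - m["a", ] + m["s", ]
    qp <- function(v) which(v > mean(v))
    for (cand in c("c1", "c2", "c3")) {
      shared <- intersect(qp(lambda), qp(m[cand, ]))
      oracle <- sum(m[cand, shared]) / sum(lambda[qp(lambda)])
      expect_equal(score_halinf(wv, q, cand), oracle, tolerance = 1e-12)
    }
  }
})

test_that("PPMI induction scores by subject co-occurrence alone", {
  corp <- nlelp_corpus(c(rep(list(c("s1", "hug")), 5),
                         rep(list(c("s2", "jeer")), 5)))
  vocab <- build_vocab(corp)
  ppmi <- build_ppmi(corp, vocab, 2)
  expect_gt(score_ppmi(ppmi, "s1", "hug"), 0)
  expect_equal(score_ppmi(ppmi, "s1", "jeer"), 0)
  # exhaustive scoring: the co-occurring action is the arg-max
  cands <- c("hug", "jeer")
  expect_equal(cands[which.max(score_ppmi(ppmi, "s1", cands))], "hug")
  expect_warning(sc <- score_ppmi(ppmi, "nobody", "hug"), "not in vocabulary")
  expect_equal(sc, 0)
})

test_that("ranking excludes query words and respects the filter", {
  toks <- c("a", "b", "s", paste0("v", 1:4))
  rv <- random_vectors(toks, 6, seed = 21)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  lex <- data.frame(token = toks,
                    pos = c("noun", "verb", "noun", rep("verb", 4)))
  filt <- candidate_filter(lex)
  r <- rank_candidates("cosine", rv, q, filter = filt)
  expect_setequal(r$candidates, paste0("v", 1:4))
  expect_false(any(c("a", "b", "s") %in% r$candidates))
  # a filter that excludes everything yields an empty ranking
  none <- candidate_filter(lex, allowed = "adjective")
  expect_warning(r0 <- rank_candidates("cosine", rv, q, filter = none),
                 "no candidates")
  expect_length(r0$candidates, 0L)
})

test_that("a candidate equal to the target ranks first under cosine", {
  m <- matrix(c(1, 0,
                0, 1,
                1, 1,
                0, 0.1,
                2, 0.2), nrow = 5, byrow = TRUE,
              dimnames = list(c("b", "a", "s", "v1", "v2"), NULL))
  m["v2", ] <- m["b", ] - m["a", ] + m["s", ]  # equals the target exactly
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  r <- rank_candidates("cosine", wv, q)
  expect_identical(r$candidates[1], "v2")
  expect_equal(r$scores[1], 1)
})

test_that("rankings equal a brute-force scoring plus stable sort oracle", {
  toks <- c("al", "be", "st", sprintf("w%02d", 1:47))
  rv <- random_vectors(toks, 10, seed = 33)
  q <- list(alpha = "al", beta = "be", alpha_star = "st")
  cands <- sprintf("w%02d", 1:47)
  for (engine in c("cosine", "cosmul", "halinf")) {
    r <- rank_candidates(engine, rv, q, top_k = 1000)
    scores <- vapply(cands, function(cand) {
      switch(engine,
             cosine = score_cosine(rv, q, cand),
             cosmul = score_cosmul(rv, q, cand),
             halinf = score_halinf(rv, q, cand))
    }, numeric(1))
    ord <- order(-scores, match(cands, toks))
    expect_identical(r$candidates, cands[ord])
    expect_equal(r$scores, unname(scores[ord]))
    expect_false(is.unsorted(rev(r$scores)))
  }
})

test_that("cosine ranking is invariant to positive per-vector scaling", {
  toks <- c("a", "b", "s", paste0("c", 1:12))
  rv <- random_vectors(toks, 6, seed = 44)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  r1 <- rank_candidates("cosine", rv, q)
  m2 <- rv$vectors
  set.seed(45)
  # candidate scaling only: the additive target itself is not
  # scale-invariant in the query words, but candidates are
  scale <- runif(12, 0.1, 10)
  m2[paste0("c", 1:12), ] <- m2[paste0("c", 1:12), ] * scale
  r2 <- rank_candidates("cosine", word_vectors(m2), q)
  expect_identical(r1$candidates, r2$candidates)
})

test_that("ties break by ascending vocabulary order deterministically", {
  m <- matrix(c(1, 0,
                0, 1,
                1, 1,
                2, 2,
                4, 4,
                1, 3), nrow = 6, byrow = TRUE,
              dimnames = list(c("b", "a", "s", "v1", "v2", "v3"), NULL))
  wv <- word_vectors(m)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  r <- rank_candidates("cosine", wv, q)
  # v1 and v2 are parallel (identical cosine): v1 precedes v2
  expect_equal(which(r$candidates == "v1"), which(r$candidates == "v2") - 1L)
  r_again <- rank_candidates("cosine", wv, q)
  expect_identical(r$candidates, r_again$candidates)
  expect_identical(r$scores, r_again$scores)
})

test_that("engines reject incompatible representations", {
  rv <- random_vectors(c("a", "b", "s", "c"), 4, seed = 2)
  corp <- nlelp_corpus(list(c("a", "b")))
  ppmi <- build_ppmi(corp, build_vocab(corp), 1)
  q <- list(alpha = "a", beta = "b", alpha_star = "s")
  expect_error(rank_candidates("ppmi", rv, q), "requires a ppmi_matrix")
  expect_error(rank_candidates("cosine", ppmi, q), "requires a word_vectors")
})

test_that("every engine runs on the improved-HAL compatibility grid", {
  fx <- benchmark_fixture()
  hal <- build_hal(fx$world$corpus, fx$vocab, 5)
  hal_vec <- as_word_vectors(hal)
  q <- fx$queries[1, ]
  for (rep in list(hal_vec, fx$cbow)) {
    for (engine in c("cosine", "cosmul", "halinf")) {
      r <- rank_candidates(engine, rep, q, filter = fx$filter, top_k = 10)
      expect_s3_class(r, "ranked_result")
      expect_gt(length(r$candidates), 0L)
    }
  }
})
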