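test_that("reciprocal rank finds the first relevant candidate", {
  expect_equal(reciprocal_rank(c("x", "y"), "x"), 1)
  expect_equal(reciprocal_rank(c("x", "y"), "y"), 0.5)
  expect_equal(reciprocal_rank(c("x", "y"), "z"), 0)
  expect_equal(reciprocal_rank(character(0), "z"), 0)
  # linear-scan oracle on random rankings
  set.seed(91)
  for (rep in 1:100) {
    cands <- sample(letters, 10)
    rel <- sample(letters, 4)
    pos <- NA
    for (i in seq_along(cands)) if (cands[i] %in% rel) { pos <- i; break }
    expect_equal(reciprocal_rank(cands, rel),
                 if (is.na(pos)) 0 else 1 / pos)
  }
})

test_that("MRR averages reciprocal ranks", {
  ranked <- list(c("g", "x"), c("x", "g"), c("x", "y", "z", "g"))
  golds <- list("g", "g", "g")
  expect_equal(mrr(ranked, golds), (1 + 1 / 2 + 1 / 4) / 3)
  expect_equal(mrr(ranked, golds), 7 / 12)
  expect_equal(mrr(list(c("g"), c("g")), list("g", "g")), 1)
  expect_error(mrr(list(), list()), "empty")
  # averaging oracle over 100 random queries
  set.seed(92)
  ranked <- replicate(100, sample(letters, 8), simplify = FALSE)
  golds <- replicate(100, sample(letters, 3), simplify = FALSE)
  oracle <- mean(mapply(reciprocal_rank, ranked, golds))
  expect_equal(mrr(ranked, golds), oracle)
})

test_that("precision at n divides by n even when candidates run short", {
  expect_equal(prec_at_n(c("a", "g1", "b", "g2", "c"), c("g1", "g2"), 5), 0.4)
  expect_equal(prec_at_n(c("a", "b"), c("z"), 5), 0)
  # fewer than n candidates: denominator stays n
  expect_equal(prec_at_n(c("g1"), c("g1"), 5), 0.2)
  # set-intersection oracle
  set.seed(93)
  for (rep in 1:100) {
    cands <- sample(letters, 12)
    rel <- sample(letters, 5)
    n <- sample(1:10, 1)
    expect_equal(prec_at_n(cands, rel, n),
                 length(intersect(cands[seq_len(min(n, 12))], rel)) / n)
  }
})

# A 2-subject world whose action vectors are built so that every gold
# action is (near) parallel to its query's analogy target.
ceiling_fixture <- function() {
  subjects <- c("s1", "s2")
  actions <- c("a1", "a2", "a3", "a4")
  cells <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, TRUE),
                  nrow = 4, dimnames = list(actions, subjects))
  lr <- lr_matrix(cells, c(s1 = "c1", s2 = "c2"))
  m <- rbind(s1 = c(10, 0, 0, 0, 0, 0),
             s2 = c(0, 10, 0, 0, 0, 0),
             a1 = c(10, 0, 1, 0, 0, 0),
             a2 = c(10, 0, 0, 1, 0, 0),
             a3 = c(0, 10, 0, 0, 1, 0),
             a4 = c(0, 10, 0, 0, 0, 1))
  list(lr = lr, wv = word_vectors(m),
       filter = candidate_filter(data.frame(
         token = c(subjects, actions),
         pos = c("noun", "noun", rep("verb", 4)))))
}

test_that("a constructed geometric ceiling reaches perfect precision", {
  fx <- ceiling_fixture()
  q <- generate_queries(fx$lr)
  part <- suppressWarnings(partition_queries(q, 0, 10, seed = 1))
  report <- run_experiment(part, "cosine", list(toy = fx$wv),
                           filter = fx$filter, n_values = 1L)
  agg <- report$results[[1]]$aggregates
  expect_equal(agg$prec_at_1[agg$scope == "overall"], 1)
  expect_equal(agg$mrr[agg$scope == "overall"], 1)
})

test_that("an empty engine list yields an empty report", {
  fx <- ceiling_fixture()
  q <- generate_queries(fx$lr)
  part <- suppressWarnings(partition_queries(q, 0, 5, seed = 1))
  report <- run_experiment(part, character(0), list(toy = fx$wv))
  expect_length(report$results, 0L)
  expect_output(print(report), "empty")
})

test_that("aggregates equal query-weighted means over member subsets", {
  fx <- benchmark_fixture()
  report <- run_experiment(fx$partition, "ppmi", list(ppmi = fx$ppmi),
                           filter = fx$filter)
  res <- report$results[[1]]
  per <- res$per_subset[res$per_subset$n_queries > 0, ]
  agg <- res$aggregates
  for (scope in c("overall", "within", "across")) {
    keys <- switch(scope,
                   overall = fx$partition$subset_keys,
                   within = fx$partition$within_keys,
                   across = setdiff(fx$partition$subset_keys,
                                    fx$partition$within_keys))
    sub <- per[per$subset %in% keys, ]
    for (col in c("prec_at_5", "prec_at_10", "mrr")) {
      pooled <- sum(sub[[col]] * sub$n_queries) / sum(sub$n_queries)
      expect_equal(agg[[col]][agg$scope == scope], pooled,
                   tolerance = 1e-12)
    }
  }
  # all metrics bounded in [0, 1]; accounting adds up
  vals <- unlist(per[c("prec_at_5", "prec_at_10", "mrr")])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(res$evaluated + res$skipped, nrow(fx$partition$test))
})

test_that("out-of-vocabulary queries are skipped and counted", {
  fx <- ceiling_fixture()
  q <- generate_queries(fx$lr)
  part <- suppressWarnings(partition_queries(q, 0, 10, seed = 1))
  # drop one action from the vector table: queries touching it skip
  wv_small <- word_vectors(fx$wv$vectors[rownames(fx$wv$vectors) != "a1", ])
  report <- run_experiment(part, "cosine", list(toy = wv_small),
                           filter = fx$filter, n_values = 1L)
  res <- report$results[[1]]
  expect_gt(res$skipped, 0L)
  expect_equal(res$evaluated + res$skipped, nrow(part$test))
  # everything out of vocabulary is an error
  wv_alien <- random_vectors(c("q", "r", "t"), 3, seed = 6)
  expect_error(run_experiment(part, "cosine", list(toy = wv_alien)),
               "out of vocabulary")
})

test_that("subset-averaged aggregation averages subset means unweighted", {
  fx <- benchmark_fixture()
  report <- run_experiment(fx$partition, "ppmi", list(ppmi = fx$ppmi),
                           filter = fx$filter, subset_averaged = TRUE)
  res <- report$results[[1]]
  per <- res$per_subset[res$per_subset$n_queries > 0, ]
  agg <- res$aggregates
  expect_equal(agg$mrr[agg$scope == "overall"], mean(per$mrr))
})

test_that("a sweep row equals the directly executed experiment", {
  fx <- benchmark_fixture()
  tab <- sweep_parameter("hal_window", c(2, 4), fx$world$corpus, fx$vocab,
                         fx$partition, engine = "cosine", filter = fx$filter)
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$value, c(2L, 4L))
  for (k in 1:2) {
    hal_vec <- as_word_vectors(build_hal(fx$world$corpus, fx$vocab,
                                         tab$value[k]))
    direct <- run_experiment(fx$partition, "cosine", list(h = hal_vec),
                             filter = fx$filter, n_values = 5L)
    agg <- direct$results[[1]]$aggregates
    expect_equal(tab$prec_at_5[k], agg$prec_at_5[agg$scope == "overall"])
    expect_equal(tab$mrr[k], agg$mrr[agg$scope == "overall"])
  }
  # rows are reproducible run to run
  tab2 <- sweep_parameter("hal_window", c(2, 4), fx$world$corpus, fx$vocab,
                          fx$partition, engine = "cosine",
                          filter = fx$filter)
  expect_identical(tab, tab2)
})

test_that("reports round-trip through ranked tables and JSON", {
  fx <- ceiling_fixture()
  q <- generate_queries(fx$lr)
  part <- suppressWarnings(partition_queries(q, 0, 10, seed = 1))
  direct <- run_experiment(part, "cosine", list(toy = fx$wv),
                           filter = fx$filter, n_values = c(1L, 2L))
  # re-evaluate the same rankings from the ranked-table path
  test <- part$test
  results <- lapply(seq_len(nrow(test)), function(i)
    rank_candidates("cosine", fx$wv, test[i, ], filter = fx$filter))
  path <- tempfile(fileext = ".tsv")
  write_ranked_tsv(results, path)
  ranked <- read.delim(path, stringsAsFactors = FALSE)
  indirect <- evaluate_rankings(ranked, test, fx$lr, n_values = c(1L, 2L))
  d_agg <- direct$results[[1]]$aggregates
  i_agg <- indirect$results[[1]]$aggregates
  for (col in c("prec_at_1", "prec_at_2", "mrr"))
    expect_equal(i_agg[[col]][i_agg$scope == "overall"],
                 d_agg[[col]][d_agg$scope == "overall"])
  json <- tempfile(fileext = ".json")
  txt <- tempfile(fileext = ".txt")
  write_report(direct, json, txt)
  parsed <- jsonlite::read_json(json)
  expect_equal(length(parsed$results), 1L)
  expect_true(any(grepl("prec_at", readLines(txt))))
})
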