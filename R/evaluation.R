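#' Reciprocal rank of the first relevant candidate
#'
#' @param result a [rank_candidates()] `ranked_result` (or a character
#'   vector of ranked candidates).
#' @param relevant character set of gold relevant actions.
#' @return `1 / rank` of the first relevant candidate; 0 when none
#'   appears (including beyond the ranking truncation).
#' @export
reciprocal_rank <- function(result, relevant) {
  cands <- if (inherits(result, "ranked_result")) result$candidates else result
  pos <- which(cands %in% relevant)
  if (length(pos) == 0L) 0 else 1 / pos[1L]
}

#' Mean reciprocal rank over a query set
#'
#' @param results list of `ranked_result`s (or candidate vectors).
#' @param golds list of gold relevant sets, parallel to `results`.
#' @return Arithmetic mean of the per-query reciprocal ranks.
#' @export
mrr <- function(results, golds) {
  if (length(results) == 0L) stop("empty query set")
  if (length(results) != length(golds))
    stop("results and golds must have equal length")
  mean(mapply(reciprocal_rank, results, golds))
}

#' Precision at n
#'
#' Fraction of the top-n ranked candidates that are gold-relevant. The
#' denominator stays `n` even when fewer than `n` candidates exist.
#'
#' @inheritParams reciprocal_rank
#' @param n cut-off, >= 1.
#' @return Value in `[0, 1]`.
#' @export
prec_at_n <- function(result, relevant, n) {
  stopifnot(n >= 1L)
  cands <- if (inherits(result, "ranked_result")) result$candidates else result
  sum(head(cands, n) %in% relevant) / n
}

# Shared aggregation: per-subset metric means plus overall/within/across
# aggregates (query-pooled, or unweighted subset means).
summarize_metrics <- function(per_query, subset_of, subset_keys, within_keys,
                              metric_cols, subset_averaged = FALSE) {
  per_subset <- do.call(rbind, lapply(subset_keys, function(key) {
    rows <- subset_of == key
    out <- data.frame(subset = key, n_queries = sum(rows))
    out[metric_cols] <- if (any(rows))
      as.list(colMeans(per_query[rows, , drop = FALSE]))
    else as.list(rep(NA_real_, length(metric_cols)))
    out
  }))
  scope_rows <- list(overall = rep(TRUE, length(subset_of)),
                     within = subset_of %in% within_keys,
                     across = !(subset_of %in% within_keys))
  aggregates <- do.call(rbind, lapply(names(scope_rows), function(scope) {
    rows <- scope_rows[[scope]]
    out <- data.frame(scope = scope, n_queries = sum(rows))
    if (!any(rows)) {
      out[metric_cols] <- NA_real_
    } else if (subset_averaged) {
      keys <- switch(scope, within = within_keys,
                     across = setdiff(subset_keys, within_keys), subset_keys)
      sub <- per_subset[per_subset$subset %in% keys &
                          per_subset$n_queries > 0L, metric_cols,
                        drop = FALSE]
      out[metric_cols] <- as.list(colMeans(sub))
    } else {
      out[metric_cols] <- as.list(colMeans(per_query[rows, , drop = FALSE]))
    }
    out
  }))
  list(per_subset = per_subset, aggregates = aggregates)
}

eval_combos <- function(engines, representations) {
  combos <- list()
  for (engine in engines) {
    for (rep_name in names(representations)) {
      rep <- representations[[rep_name]]
      if (inherits(rep, "hal_matrix")) rep <- as_word_vectors(rep)
      compatible <- if (engine == "ppmi") inherits(rep, "ppmi_matrix")
                    else inherits(rep, "word_vectors")
      if (compatible)
        combos[[length(combos) + 1L]] <-
          list(engine = engine, rep_name = rep_name, rep = rep)
    }
  }
  combos
}

#' Run an engine-comparison experiment
#'
#' Evaluates every compatible (engine, representation) pair on the test
#' split of a query partition: per category-pair subset and in aggregate,
#' prec@n for each requested n and MRR. Queries with any
#' out-of-vocabulary word are skipped and counted, not scored as
#' failures. Aggregates are query-pooled by default (equivalently,
#' query-weighted means over member subsets); `subset_averaged = TRUE`
#' averages subset means unweighted instead.
#'
#' @param partition a [partition_queries()] result.
#' @param engines character vector of engine names.
#' @param representations named list of representations
#'   ([word_vectors()], `hal_matrix`, or [build_ppmi()] matrices).
#' @param filter a [candidate_filter()] or `NULL`.
#' @param n_values precision cut-offs (default 5 and 10).
#' @param top_k ranking truncation depth (default 100); reciprocal rank
#'   beyond it is 0.
#' @param subset_averaged aggregate by unweighted subset means.
#' @return An object of class `eval_report`.
#' @export
run_experiment <- function(partition, engines, representations, filter = NULL,
                           n_values = c(5L, 10L), top_k = 100L,
                           subset_averaged = FALSE) {
  stopifnot(inherits(partition, "query_partition"))
  test <- partition$test
  gold_map <- attr(test, "gold")
  if (nrow(test) == 0L) stop("empty test split")
  combos <- eval_combos(engines, representations)
  metric_cols <- c(paste0("prec_at_", n_values), "mrr")

  results <- lapply(combos, function(combo) {
    toks <- representation_tokens(combo$rep)
    need_oov <- if (combo$engine == "ppmi") list(test$alpha_star)
                else list(test$alpha, test$beta, test$alpha_star)
    in_vocab <- Reduce(`&`, lapply(need_oov, `%in%`, table = toks))
    evaluated_idx <- which(in_vocab)
    if (length(evaluated_idx) == 0L)
      stop("all test queries are out of vocabulary for engine '",
           combo$engine, "' + representation '", combo$rep_name, "'")
    log_debug("evaluating ", combo$engine, " + ", combo$rep_name, " on ",
              length(evaluated_idx), " queries")

    per_query <- matrix(NA_real_, length(evaluated_idx), length(metric_cols),
                        dimnames = list(NULL, metric_cols))
    for (k in seq_along(evaluated_idx)) {
      i <- evaluated_idx[k]
      q <- list(alpha = test$alpha[i], beta = test$beta[i],
                alpha_star = test$alpha_star[i])
      rel <- gold_map[[q$alpha_star]]
      r <- rank_candidates(combo$engine, combo$rep, q, filter = filter,
                           top_k = top_k)
      per_query[k, ] <- c(vapply(n_values, function(n)
                                 prec_at_n(r, rel, n), numeric(1)),
                          reciprocal_rank(r, rel))
    }

    summ <- summarize_metrics(per_query, test$subset[evaluated_idx],
                              partition$subset_keys, partition$within_keys,
                              metric_cols, subset_averaged)

    list(engine = combo$engine, representation = combo$rep_name,
         per_subset = summ$per_subset, aggregates = summ$aggregates,
         evaluated = length(evaluated_idx),
         skipped = nrow(test) - length(evaluated_idx))
  })

  structure(list(results = results, n_values = as.integer(n_values),
                 config = list(top_k = as.integer(top_k),
                               subset_averaged = subset_averaged,
                               engines = engines,
                               representations = names(representations),
                               n_test = nrow(test),
                               partition_seed = partition$seed)),
            class = "eval_report")
}

#' Evaluate pre-computed rankings from a ranked-output table
#'
#' Takes the `(query_id, rank, candidate, score, engine)` table produced
#' by [write_ranked_tsv()] (or the inference CLI stage) together with the
#' query set it was ranked for, and computes the same per-subset and
#' aggregate metrics as [run_experiment()]. Gold relevance and category
#' labels come from the consensus matrix.
#'
#' @param ranked data.frame with columns `query_id`, `rank`, `candidate`,
#'   `engine` (as read from a ranked TSV).
#' @param queries the `nlelp_queries` set the ids refer to (row numbers).
#' @param lr the consensus [lr_matrix()] supplying gold sets and
#'   categories.
#' @param n_values precision cut-offs.
#' @param subset_averaged aggregate by unweighted subset means.
#' @return An `eval_report` with one result entry.
#' @export
evaluate_rankings <- function(ranked, queries, lr, n_values = c(5L, 10L),
                              subset_averaged = FALSE) {
  stopifnot(is.data.frame(ranked), inherits(queries, "nlelp_queries"),
            inherits(lr, "lr_matrix"))
  metric_cols <- c(paste0("prec_at_", n_values), "mrr")
  cats <- lr$subject_category
  levels_cat <- unique(unname(cats))
  subset_keys <- as.vector(outer(levels_cat, levels_cat, subset_key))
  within_keys <- subset_key(levels_cat, levels_cat)

  ord <- order(ranked$query_id, ranked$rank)
  ranked <- ranked[ord, , drop = FALSE]
  by_query <- split(ranked, ranked$query_id)
  qids <- as.integer(names(by_query))
  if (any(qids < 1L | qids > nrow(queries)))
    stop("ranked table refers to query ids outside the query set")
  per_query <- matrix(NA_real_, length(qids), length(metric_cols),
                      dimnames = list(NULL, metric_cols))
  for (k in seq_along(qids)) {
    i <- qids[k]
    cands <- by_query[[k]]$candidate
    rel <- lr$actions[lr$cells[, queries$alpha_star[i]]]
    per_query[k, ] <- c(vapply(n_values, function(n)
                               prec_at_n(cands, rel, n), numeric(1)),
                        reciprocal_rank(cands, rel))
  }
  subset_of <- subset_key(cats[queries$alpha[qids]],
                          cats[queries$alpha_star[qids]])
  summ <- summarize_metrics(per_query, subset_of, subset_keys, within_keys,
                            metric_cols, subset_averaged)
  engine <- if (nrow(ranked)) ranked$engine[1L] else "unknown"
  structure(list(results = list(list(engine = engine,
                                     representation = "precomputed",
                                     per_subset = summ$per_subset,
                                     aggregates = summ$aggregates,
                                     evaluated = length(qids),
                                     skipped = nrow(queries) - length(qids))),
                 n_values = as.integer(n_values),
                 config = list(subset_averaged = subset_averaged,
                               source = "ranked-table",
                               n_test = nrow(queries))),
            class = "eval_report")
}

report_table <- function(report) {
  do.call(rbind, lapply(report$results, function(res) {
    agg <- res$aggregates
    row <- data.frame(method = paste(res$representation, res$engine,
                                     sep = " + "),
                      stringsAsFactors = FALSE)
    for (scope in c("within", "across")) {
      a <- agg[agg$scope == scope, , drop = FALSE]
      for (col in setdiff(names(agg), c("scope", "n_queries")))
        row[[paste(scope, col, sep = ".")]] <-
          if (nrow(a)) a[[col]] else NA_real_
    }
    row$evaluated <- res$evaluated
    row$skipped <- res$skipped
    row
  }))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  if (length(x$results) == 0L) {
    cat("<eval_report> empty (no engine/representation combinations)\n")
    return(invisible(x))
  }
  tab <- report_table(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  cat("<eval_report> within/across-category ranked-retrieval metrics\n")
  print(format(tab), row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes a machine-readable JSON report and, optionally, the aligned
#' text table alongside it.
#'
#' @param report an `eval_report`.
#' @param json_path output JSON path.
#' @param text_path optional output path for the text table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, text_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(config = report$config, n_values = report$n_values,
                  results = report$results)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(text_path)) {
    txt <- utils::capture.output(print(report))
    writeLines(txt, text_path, useBytes = TRUE)
  }
  invisible(json_path)
}

#' Sensitivity sweep over a representation hyper-parameter
#'
#' Re-runs one experiment per value of either the embedding dimension or
#' the HAL window size, holding everything else fixed, and tabulates
#' prec@5 and MRR (overall, query-pooled).
#'
#' @param parameter "dimension" (retrains embeddings per value) or
#'   "hal_window" (rebuilds the HAL space per value).
#' @param values parameter values to sweep (non-empty).
#' @param corpus,vocab corpus and vocabulary for representation building.
#' @param partition a [partition_queries()] result.
#' @param engine inference engine applied at every value.
#' @param filter a [candidate_filter()] or `NULL`.
#' @param cfg base [embedding_config()] (used for "dimension").
#' @param top_k ranking truncation depth.
#' @return data.frame with columns `value`, `prec_at_5`, `mrr`.
#' @export
sweep_parameter <- function(parameter = c("dimension", "hal_window"), values,
                            corpus, vocab, partition, engine = "cosine",
                            filter = NULL, cfg = embedding_config(),
                            top_k = 100L) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("values must be non-empty")
  rows <- lapply(values, function(v) {
    rep <- if (parameter == "dimension") {
      cfg$dim <- as.integer(v)
      train_embeddings(corpus, vocab, cfg)
    } else {
      as_word_vectors(build_hal(corpus, vocab, as.integer(v)))
    }
    report <- run_experiment(partition, engine, setNames(list(rep), "swept"),
                             filter = filter, n_values = 5L, top_k = top_k)
    agg <- report$results[[1L]]$aggregates
    overall <- agg[agg$scope == "overall", , drop = FALSE]
    data.frame(value = as.integer(v), prec_at_5 = overall$prec_at_5,
               mrr = overall$mrr)
  })
  do.call(rbind, rows)
}
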