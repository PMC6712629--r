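#' Analogy query sets
#'
#' An analogy query <alpha:beta>::<alpha_star:?> asks which action pairs
#' with subject `alpha_star` the way action `beta` pairs with subject
#' `alpha`. A query set is a data.frame with columns `alpha`, `beta`,
#' `alpha_star` and `problem` ("within" when the two subjects share a
#' life-domain category, "across" otherwise), carrying as attributes the
#' gold relevance sets (`gold`: subject -> all consensus-marked actions)
#' and the subject category map (`categories`).
#'
#' @name nlelp_queries
NULL

new_queries <- function(df, gold, categories) {
  rownames(df) <- NULL
  structure(df, gold = gold, categories = categories,
            class = c("nlelp_queries", "data.frame"))
}

#' Gold relevant actions for a subject
#'
#' @param queries an `nlelp_queries` set (or `query_partition` split).
#' @param subject subject token.
#' @return Character vector of consensus-marked actions for the subject.
#' @export
relevant_actions <- function(queries, subject) {
  gold <- attr(queries, "gold")
  if (is.null(gold)) stop("query set carries no gold relevance sets")
  acts <- gold[[subject]]
  if (is.null(acts)) character(0) else acts
}

#' Generate analogy queries from a consensus matrix
#'
#' One query is produced for every seed pattern <alpha:beta> (marked
#' cell) and every other subject alpha_star whose consensus row is
#' non-empty. The gold relevant set of a query is exactly the set of
#' actions marked for alpha_star; the `problem` label is "within" when
#' alpha and alpha_star share a category.
#'
#' @param consensus an [lr_matrix()].
#' @return An `nlelp_queries` data.frame (possibly with zero rows).
#' @export
generate_queries <- function(consensus) {
  stopifnot(inherits(consensus, "lr_matrix"))
  seeds <- seed_patterns(consensus)
  marked <- colSums(consensus$cells) > 0L
  targets <- consensus$subjects[marked]
  gold <- setNames(lapply(targets, function(s) {
    consensus$actions[consensus$cells[, s]]
  }), targets)
  cats <- consensus$subject_category
  if (nrow(seeds) == 0L || length(targets) < 2L) {
    return(new_queries(data.frame(alpha = character(0), beta = character(0),
                                  alpha_star = character(0),
                                  problem = character(0),
                                  stringsAsFactors = FALSE),
                       gold, cats))
  }
  grid <- expand.grid(seed = seq_len(nrow(seeds)),
                      alpha_star = targets,
                      stringsAsFactors = FALSE)
  grid <- grid[seeds$subject[grid$seed] != grid$alpha_star, , drop = FALSE]
  df <- data.frame(alpha = seeds$subject[grid$seed],
                   beta = seeds$action[grid$seed],
                   alpha_star = grid$alpha_star,
                   stringsAsFactors = FALSE)
  df$problem <- ifelse(cats[df$alpha] == cats[df$alpha_star],
                       "within", "across")
  new_queries(df, gold, cats)
}

#' Expand query actions through a synonym map
#'
#' For every query whose action beta has entries in the synonym map,
#' additional queries are emitted with beta replaced by each expansion
#' token; the originals are retained and exact duplicates (same alpha,
#' beta, alpha_star) are removed. When a vocabulary is supplied,
#' expansions absent from it are skipped with a warning, since
#' vector-based engines cannot score them.
#'
#' @param queries an `nlelp_queries` set.
#' @param synonym_map named list action -> character vector of expansions
#'   (see [read_synonym_map()]).
#' @param vocab optional [build_vocab()] vocabulary used to screen
#'   expansion tokens.
#' @return The expanded `nlelp_queries` set.
#' @export
expand_actions <- function(queries, synonym_map, vocab = NULL) {
  stopifnot(inherits(queries, "nlelp_queries"))
  if (length(synonym_map) == 0L || nrow(queries) == 0L) return(queries)
  hit <- queries$beta %in% names(synonym_map)
  if (!any(hit)) return(queries)
  exp_list <- synonym_map[queries$beta[hit]]
  if (!is.null(vocab)) {
    all_exp <- unique(unlist(exp_list, use.names = FALSE))
    oov <- setdiff(all_exp, vocab$tokens)
    if (length(oov)) {
      warning(length(oov), " expansion token(s) absent from vocabulary, ",
              "skipped: ", paste(head(oov, 5L), collapse = ", "),
              if (length(oov) > 5L) ", ...")
      exp_list <- lapply(exp_list, setdiff, y = oov)
    }
  }
  n_exp <- lengths(exp_list)
  src <- which(hit)[rep(seq_along(exp_list), n_exp)]
  extra <- data.frame(alpha = queries$alpha[src],
                      beta = unlist(exp_list, use.names = FALSE),
                      alpha_star = queries$alpha_star[src],
                      problem = queries$problem[src],
                      stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(queries)[, c("alpha", "beta", "alpha_star", "problem")],
               extra)
  out <- out[!duplicated(out[, c("alpha", "beta", "alpha_star")]), , drop = FALSE]
  new_queries(out, attr(queries, "gold"), attr(queries, "categories"))
}

subset_key <- function(cat_alpha, cat_alpha_star) {
  paste(cat_alpha, cat_alpha_star, sep = "->")
}

#' Partition queries into category-pair subsets with train/test samples
#'
#' Queries are keyed by the ordered pair (category(alpha),
#' category(alpha_star)); with 5 categories this yields 25 subsets, 5
#' within-category and 20 across-category. From each subset
#' `per_subset_train` queries are sampled for the training split and
#' `per_subset_test` disjoint queries for the test split, without
#' replacement. Subsets smaller than the request are downsampled to
#' availability with a warning. Deterministic under `seed`.
#'
#' @param queries an `nlelp_queries` set with category attributes.
#' @param per_subset_train training queries per subset (>= 0).
#' @param per_subset_test test queries per subset (>= 0).
#' @param seed integer random seed.
#' @return An object of class `query_partition`: list with `train` and
#'   `test` (`nlelp_queries` with an extra `subset` column), `subset_keys`
#'   (all 25 ordered pairs), `counts` (per-subset totals), and `seed`.
#' @export
partition_queries <- function(queries, per_subset_train, per_subset_test,
                              seed = 1L) {
  stopifnot(inherits(queries, "nlelp_queries"))
  cats <- attr(queries, "categories")
  if (is.null(cats)) stop("query set carries no category map")
  levels_cat <- unique(unname(cats))
  keys <- as.vector(outer(levels_cat, levels_cat, subset_key))
  per_subset_train <- as.integer(per_subset_train)
  per_subset_test <- as.integer(per_subset_test)
  stopifnot(per_subset_train >= 0L, per_subset_test >= 0L)

  key_of <- subset_key(cats[queries$alpha], cats[queries$alpha_star])
  idx_by_key <- split(seq_len(nrow(queries)), factor(key_of, levels = keys))

  tr_idx <- te_idx <- integer(0)
  short <- character(0)
  with_seed(seed, {
    for (k in keys) {
      idx <- idx_by_key[[k]]
      if (length(idx) < per_subset_train + per_subset_test)
        short <- c(short, k)
      perm <- if (length(idx)) idx[sample.int(length(idx))] else integer(0)
      ntr <- min(per_subset_train, length(perm))
      nte <- min(per_subset_test, length(perm) - ntr)
      tr_idx <- c(tr_idx, perm[seq_len(ntr)])
      te_idx <- c(te_idx, if (nte > 0L) perm[ntr + seq_len(nte)] else integer(0))
    }
  })
  if (length(short))
    warning("subsets smaller than train+test request, downsampled: ",
            paste(short, collapse = ", "))

  take <- function(idx) {
    df <- as.data.frame(queries)[idx, c("alpha", "beta", "alpha_star", "problem"),
                                 drop = FALSE]
    df$subset <- key_of[idx]
    new_queries(df, attr(queries, "gold"), cats)
  }
  within_keys <- subset_key(levels_cat, levels_cat)
  structure(list(train = take(tr_idx), test = take(te_idx),
                 subset_keys = keys, within_keys = within_keys,
                 counts = setNames(lengths(idx_by_key), keys),
                 seed = as.integer(seed)),
            class = "query_partition")
}

#' @export
print.query_partition <- function(x, ...) {
  cat(sprintf("<query_partition> %d subsets (%d within, %d across); train %d, test %d\n",
              length(x$subset_keys), length(x$within_keys),
              length(x$subset_keys) - length(x$within_keys),
              nrow(x$train), nrow(x$test)))
  invisible(x)
}

#' Read a synonym-expansion map from TSV
#'
#' Two columns: action token, comma-separated expansion tokens.
#'
#' @param path TSV path.
#' @return Named list action -> character vector.
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop("cannot read synonym map: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("format error in ", path, ": need 2 tab columns")
  setNames(lapply(df[[2L]], function(s) {
    out <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    out[nzchar(out)]
  }), df[[1L]])
}

#' Write queries to TSV
#'
#' Columns: alpha, beta, alpha_star, problem.
#'
#' @param queries an `nlelp_queries` set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  stopifnot(inherits(queries, "nlelp_queries"))
  write.table(as.data.frame(queries)[, c("alpha", "beta", "alpha_star", "problem")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read queries from TSV
#'
#' @param path TSV with columns alpha, beta, alpha_star, problem.
#' @param lr optional [lr_matrix()]; when supplied, gold relevance sets
#'   and category labels are attached from its consensus rows.
#' @return An `nlelp_queries` set.
#' @export
read_queries <- function(path, lr = NULL) {
  if (!file.exists(path)) stop("cannot read queries: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  need <- c("alpha", "beta", "alpha_star", "problem")
  if (!all(need %in% names(df)))
    stop("format error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  gold <- NULL
  cats <- NULL
  if (!is.null(lr)) {
    stopifnot(inherits(lr, "lr_matrix"))
    marked <- colSums(lr$cells) > 0L
    targets <- lr$subjects[marked]
    gold <- setNames(lapply(targets, function(s) lr$actions[lr$cells[, s]]),
                     targets)
    cats <- lr$subject_category
  }
  new_queries(df[, need], gold, cats)
}
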