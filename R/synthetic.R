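# Evaluate expr with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic pattern-mining world
#'
#' Describes a corpus generator that emulates the annotation design of a
#' seed-pattern study: subjects grouped into life-domain categories,
#' actions paired with subjects through a planted logical-relationship
#' matrix, and sentences in which one planted (subject, action) pair
#' co-occurs within a short window against background noise vocabulary.
#'
#' @param n_subjects_per_category subjects per category (positive integer).
#' @param categories category names (default the five canonical
#'   life domains).
#' @param n_actions number of action tokens.
#' @param pairing_density fraction of subject-action cells marked logical,
#'   in (0, 1].
#' @param n_sentences number of sentences to generate.
#' @param noise_vocab_size size of the background noise vocabulary
#'   (0 disables noise entirely).
#' @param window_gap_max maximum number of noise tokens between the
#'   planted subject and action (also bounds the noise prefix/suffix).
#' @param n_casual_verbs number of casual-verb confounder tokens: verbs
#'   that habitually co-occur with one particular subject without
#'   constituting a logical pattern (think <mom:nags>). Each is attached
#'   to a uniformly drawn subject. Disabled when `noise_vocab_size` is 0.
#' @param casual_verb_rate per-sentence probability that a sentence of
#'   the attached subject carries one of its casual verbs.
#' @param seed integer random seed; the same seed yields a byte-identical
#'   world and corpus.
#' @return An object of class `synthetic_world_spec`.
#' @export
synthetic_world_spec <- function(n_subjects_per_category = 2L,
                                 categories = c("family", "love", "school",
                                                "work", "social"),
                                 n_actions = 20L,
                                 pairing_density = 0.5,
                                 n_sentences = 5000L,
                                 noise_vocab_size = 100L,
                                 window_gap_max = 2L,
                                 n_casual_verbs = 10L,
                                 casual_verb_rate = 0.015,
                                 seed = 1L) {
  spec <- list(n_subjects_per_category = as.integer(n_subjects_per_category),
               categories = as.character(categories),
               n_actions = as.integer(n_actions),
               pairing_density = as.numeric(pairing_density),
               n_sentences = as.integer(n_sentences),
               noise_vocab_size = as.integer(noise_vocab_size),
               window_gap_max = as.integer(window_gap_max),
               n_casual_verbs = as.integer(n_casual_verbs),
               casual_verb_rate = as.numeric(casual_verb_rate),
               seed = as.integer(seed))
  if (spec$n_subjects_per_category < 1L || spec$n_actions < 1L ||
      spec$n_sentences < 1L)
    stop("all counts must be positive")
  if (spec$noise_vocab_size < 0L || spec$window_gap_max < 0L)
    stop("noise_vocab_size and window_gap_max must be >= 0")
  if (spec$n_casual_verbs < 0L)
    stop("n_casual_verbs must be >= 0")
  if (spec$casual_verb_rate < 0 || spec$casual_verb_rate > 1)
    stop("casual_verb_rate must be in [0, 1]")
  if (!(spec$pairing_density > 0 && spec$pairing_density <= 1))
    stop("pairing_density must be in (0, 1]")
  if (length(spec$categories) < 1L || anyDuplicated(spec$categories))
    stop("categories must be distinct and non-empty")
  structure(spec, class = "synthetic_world_spec")
}

#' Plant a synthetic logical-relationship matrix
#'
#' Marks cells of an actions x subjects grid at random. Either a global
#' `pairing_density` (fraction of all cells) or an exact per-category
#' seed count can be requested; the latter reproduces a published
#' per-category seed distribution exactly.
#'
#' @param n_subjects_per_category integer, scalar or one per category.
#' @param categories category names.
#' @param n_actions number of actions.
#' @param pairing_density fraction of cells to mark (ignored when
#'   `seeds_per_category` is given).
#' @param seeds_per_category optional named integer vector: exact number
#'   of marked cells per category.
#' @param seed integer random seed.
#' @return An [lr_matrix()] ground truth.
#' @export
synthetic_lr_matrix <- function(n_subjects_per_category, categories, n_actions,
                                pairing_density = NULL,
                                seeds_per_category = NULL, seed = 1L) {
  n_cat <- length(categories)
  nsub <- rep_len(as.integer(n_subjects_per_category), n_cat)
  subjects <- unlist(lapply(seq_len(n_cat), function(i) {
    sprintf("%s_s%02d", categories[i], seq_len(nsub[i]))
  }))
  subject_category <- setNames(rep(categories, nsub), subjects)
  actions <- sprintf("act_%03d", seq_len(as.integer(n_actions)))
  cells <- matrix(FALSE, length(actions), length(subjects),
                  dimnames = list(actions, subjects))
  with_seed(seed, {
    if (!is.null(seeds_per_category)) {
      stopifnot(all(categories %in% names(seeds_per_category)))
      for (cat in categories) {
        cols <- which(subject_category[subjects] == cat)
        ncells <- length(actions) * length(cols)
        k <- as.integer(seeds_per_category[[cat]])
        if (k > ncells) stop("seeds_per_category exceeds cells for ", cat)
        # cover subjects first (every annotated subject carries at least
        # one pattern), then spread the remainder uniformly
        cover <- sample(cols, min(k, length(cols)))
        for (col in cover)
          cells[sample.int(length(actions), 1L), col] <- TRUE
        while (sum(cells[, cols, drop = FALSE]) < k) {
          free <- which(!cells[, cols, drop = FALSE])
          pick <- if (length(free) == 1L) free else sample(free, 1L)
          cells[cbind((pick - 1L) %% length(actions) + 1L,
                      cols[(pick - 1L) %/% length(actions) + 1L])] <- TRUE
        }
      }
    } else {
      ncells <- length(cells)
      k <- round(as.numeric(pairing_density) * ncells)
      if (k < 1L) stop("pairing_density yields zero logical cells")
      cells[sample.int(ncells, k)] <- TRUE
    }
  })
  lr_matrix(cells, subject_category)
}

#' Generate a synthetic corpus with planted subject-action structure
#'
#' Every sentence contains exactly one (subject, action) pair drawn
#' uniformly from the cells marked logical in the planted matrix. The
#' subject precedes the action, separated by at most `window_gap_max`
#' noise tokens; a noise prefix and suffix of at most the same length
#' surround the pair. The returned matrix is the ground truth of planted
#' pairings, and the part-of-speech lexicon tags subjects as nouns,
#' actions and casual verbs as verbs, and remaining noise as other.
#'
#' The noise vocabulary emulates two features of real consultation text:
#'
#' * Topical vocabulary: the noise vocabulary is partitioned into
#'   per-subject pools, and a sentence's noise tokens are drawn from the
#'   pool of its subject — discourse about a subject reuses the
#'   vocabulary of that life domain, which is what lets distributional
#'   representations place a subject near its actions.
#' * Casual-verb confounders: `n_casual_verbs` verb tokens are each
#'   attached to one random subject and inserted at a low rate into that
#'   subject's sentences. They co-occur habitually with the subject yet
#'   are not planted patterns, reproducing the rare-event false
#'   positives that plague raw pointwise-mutual-information induction.
#'
#' With `noise_vocab_size = 0` both mechanisms are disabled and each
#' sentence is exactly `"subject action"`.
#'
#' @param spec a [synthetic_world_spec()].
#' @return An object of class `nlelp_world`: list with `corpus`
#'   ([nlelp_corpus()]), `lr` ([lr_matrix()]), `pos` (data.frame
#'   `token`, `pos`), `casual_verbs` (named character: verb -> attached
#'   subject) and `spec`.
#' @export
generate_synthetic_world <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  lr <- synthetic_lr_matrix(spec$n_subjects_per_category, spec$categories,
                            spec$n_actions,
                            pairing_density = spec$pairing_density,
                            seed = spec$seed)
  seeds <- seed_patterns(lr)
  subjects <- lr$subjects
  noise_on <- spec$noise_vocab_size > 0L
  noise_tokens <- if (noise_on)
    sprintf("noise_%04d", seq_len(spec$noise_vocab_size)) else character(0)
  casual_tokens <- if (noise_on && spec$n_casual_verbs > 0L)
    sprintf("cverb_%02d", seq_len(spec$n_casual_verbs)) else character(0)
  gap <- spec$window_gap_max

  # per-subject topical pools; subjects beyond the partition fall back to
  # the whole noise vocabulary
  pools <- if (noise_on)
    split(noise_tokens, rep(seq_along(subjects),
                            length.out = length(noise_tokens)))
  else list()
  pool_of <- function(s) {
    p <- pools[[match(s, subjects)]]
    if (is.null(p) || length(p) == 0L) noise_tokens else p
  }

  out <- with_seed(spec$seed + 1L, {
    casual_map <- if (length(casual_tokens))
      setNames(sample(subjects, length(casual_tokens), replace = TRUE),
               casual_tokens) else setNames(character(0), character(0))
    cell <- sample.int(nrow(seeds), spec$n_sentences, replace = TRUE)
    sentences <- lapply(seq_len(spec$n_sentences), function(i) {
      s <- seeds$subject[cell[i]]
      a <- seeds$action[cell[i]]
      if (!noise_on) return(c(s, a))
      pool <- pool_of(s)
      draw <- function(n) if (n == 0L) character(0)
                          else sample(pool, n, replace = TRUE)
      sent <- c(draw(sample.int(gap + 1L, 1L) - 1L), s,
                draw(sample.int(gap + 1L, 1L) - 1L), a,
                draw(sample.int(gap + 1L, 1L) - 1L))
      mine <- names(casual_map)[casual_map == s]
      if (length(mine) &&
          stats::runif(1) < spec$casual_verb_rate * length(mine)) {
        at <- sample.int(length(sent) + 1L, 1L) - 1L
        sent <- append(sent, sample(mine, 1L), after = at)
      }
      sent
    })
    list(sentences = sentences, casual_map = casual_map)
  })

  pos <- data.frame(token = c(lr$subjects, lr$actions, noise_tokens,
                              casual_tokens),
                    pos = c(rep("noun", length(lr$subjects)),
                            rep("verb", length(lr$actions)),
                            rep("other", length(noise_tokens)),
                            rep("verb", length(casual_tokens))),
                    stringsAsFactors = FALSE)
  structure(list(corpus = nlelp_corpus(out$sentences, source = "synthetic"),
                 lr = lr, pos = pos, casual_verbs = out$casual_map,
                 spec = spec),
            class = "nlelp_world")
}

#' @export
print.nlelp_world <- function(x, ...) {
  cat(sprintf("<nlelp_world> %d sentences; %d subjects x %d actions, %d planted pairs\n",
              length(x$corpus), length(x$lr$subjects), length(x$lr$actions),
              sum(x$lr$cells)))
  invisible(x)
}

#' Dump the planted logical cells of a synthetic world
#'
#' Writes a TSV with columns `action`, `subject`, `category`, one row per
#' planted (subject, action) pair.
#'
#' @param world an `nlelp_world` from [generate_synthetic_world()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_world_tsv <- function(world, path) {
  stopifnot(inherits(world, "nlelp_world"))
  seeds <- seed_patterns(world$lr)
  write.table(seeds[, c("action", "subject", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a synthetic synonym-expansion map
#'
#' Emulates an ontology-based action expansion: every action receives
#' `n_expansions` synthetic synonym tokens. Used to scale a query set the
#' way knowledge-based expansion scales a real study's query pool.
#'
#' @param actions character vector of action tokens.
#' @param n_expansions expansions per action.
#' @return Named list action -> character vector of expansion tokens.
#' @export
synthetic_synonym_map <- function(actions, n_expansions) {
  n_expansions <- as.integer(n_expansions)
  stopifnot(n_expansions >= 0L)
  setNames(lapply(actions, function(a) {
    if (n_expansions == 0L) character(0)
    else sprintf("%s_syn%02d", a, seq_len(n_expansions))
  }), actions)
}
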