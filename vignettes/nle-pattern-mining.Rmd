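---
title: "Mining negative-life-event language patterns by analogical reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining negative-life-event language patterns by analogical reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Psychiatric consultation text is full of *negative-life-event language
patterns* (NLE-LPs): `<subject:action>` pairs such as `<parent:divorce>`
or `<boyfriend:break_up>` that express a stressful event. Detecting them
automatically helps triage people who may need psychiatric care, but the
pairs are non-contiguous, vary freely in wording, and annotating them is
expensive. `nlelp` implements an analogical-reasoning pipeline for
*mining* such patterns: given a small annotated seed set, it infers new
plausible `<subject:action>` pairs from distributional word
representations trained on raw text.

The central operation is the word analogy. Given a seed pattern
`<alpha:beta>` and a new subject `alpha_star`, the query
`<alpha:beta>::<alpha_star:?>` asks for actions `beta_star` standing to
`alpha_star` the way `beta` stands to `alpha`. The package builds three
word representations and four inference engines, and evaluates every
combination with ranked-retrieval metrics.

## Representations

All three representations assign each vocabulary word a vector `V(.)`;
sentences are the co-occurrence unit throughout, and no window crosses a
sentence boundary.

**HAL (hyperspace analog to language).** A `|V| x |V|` matrix of
distance-weighted counts. A window of the `n` preceding words slides
over each sentence; a context word at distance `d` from the target adds
weight `n - d + 1` to the (target, context) cell, so the adjacent word
contributes `n` and the furthest word in the window contributes 1. Rows
serve as HAL-VEC word vectors. The window holds `n` preceding words:
this is the only reading under which the adjacent word can carry weight
`n` while the furthest carries weight 1, and it is asserted by the
package's tests.

**PPMI.** Positive pointwise mutual information over window-based
co-occurrence: every ordered in-sentence position pair `(i, j)` with
`0 < |i - j| <= w` increments `count(token_i, token_j)`; with `D` the
total count, `PMI(x,y) = log( (count(x,y)/D) / ((m(x)/D)(m(y)/D)) )`
with row marginals `m`, and `PPMI = max(PMI, 0)`. The matrix is
symmetric by construction and only strictly positive scores are stored.
The natural log is used; the base rescales scores without changing any
ranking.

**CBOW / skip-gram embeddings.** Shallow log-linear models trained from
scratch (compiled code, single-threaded, deterministic under an explicit
seed). CBOW predicts the current word from the component-wise mean of
its context vectors; skip-gram uses the current word as input and
predicts each context word. The training objective is negative sampling
(default `k = 5`) against a unigram^0.75 noise distribution with a
linearly decaying learning rate — the canonical companion objective for
these architectures, which name the networks but leave the loss
unspecified. The input-side vectors are returned. CBOW's backward pass
applies the exact gradient of the mean formulation (each context vector
receives the error divided by the context size).

## Inference engines

For a query `(alpha, beta, alpha_star)`, the analogy target is

```
lambda = V(beta) - V(alpha) + V(alpha_star)
```

* **COSINE** (3CosAdd): `cos(V(c), lambda)`.
* **COSMUL** (3CosMul):
  `cos(V(c), V(beta)) * cos(V(c), V(alpha_star)) / (cos(V(c), V(alpha)) + eps)`
  with `eps = 0.001` guarding the division. Cosines are used as printed,
  without shifting into `[0, 1]`; negative cosines can therefore yield
  negative scores.
* **HAL-INF**: only "quality property" dimensions participate — for a
  vector `v`, `QP(v) = { k : v_k > mean(v) }`. The score is
  `sum over QP(lambda) ∩ QP(V(c)) of V(c)_i` divided by
  `sum over QP(lambda) of lambda_j`. The denominator runs over `lambda`
  only (the formula, not its looser prose gloss), and the mean threshold
  is applied to `lambda` verbatim even when its mean is negative; a
  lambda without usable quality mass scores 0 with a warning.
* **PPMI induction**: single-subject induction — the score of candidate
  `c` is `PPMI(alpha_star, c)`; `alpha` and `beta` are ignored.

Candidates are all vocabulary tokens passing a part-of-speech filter
(actions are verbs), *minus the query words* `alpha`, `beta`,
`alpha_star` — the universal analogy-evaluation convention, without
which `beta` trivially wins additive cosine whenever
`alpha = alpha_star`. Filtering is applied before ranking; ties break by
ascending vocabulary id so rankings are bit-reproducible; rankings are
truncated at a configurable depth (default 100), and a reciprocal rank
beyond the truncation counts as 0.

## Query sets and evaluation

Seed patterns come from a logical-relationship (LR) matrix: an
actions-by-subjects grid marked by annotators, combined across
annotators by unanimous consensus (a cell survives only when every
annotator marked it; the threshold is configurable). One query is
generated per seed `<alpha:beta>` and per other subject `alpha_star`
with a non-empty consensus row. The gold relevant set of a query is the
*whole* consensus row of `alpha_star`, not a single intended answer: any
action an annotator judged logically compatible with the subject counts
as a correct inference. Queries are labelled *within*-category when the
two subjects share a life-domain category (family, love, school, work,
social) and *across* otherwise; keyed by the ordered category pair they
fall into 25 subsets (5 within, 20 across), from which train/test splits
are sampled without replacement, deterministically under a seed.

A pluggable synonym map (standing in for an external lexical ontology)
expands query actions; expansions absent from the vocabulary are skipped
with a warning for vector engines. Only actions are expanded.

Metrics are `prec@n` (fraction of the top-`n` candidates that are gold;
the denominator stays `n` even when fewer candidates exist) and MRR
(mean over queries of the reciprocal rank of the first gold candidate).
Queries containing any out-of-vocabulary word are skipped and counted
rather than scored as zero — silent zeros would corrupt comparisons
between representations with different vocabularies, and the count keeps
the skipping auditable. Within/across aggregates are query-pooled by
default (equivalently, query-weighted means over member subsets); an
unweighted subset-mean variant is available as a flag.

## The synthetic world

`generate_synthetic_world()` builds corpora in which the pipeline's
recovery can be measured against a known ground truth. A planted LR
matrix marks a `pairing_density` fraction of subject-action cells
logical; each sentence carries exactly one planted pair, drawn uniformly
over marked cells, with the subject preceding the action and at most
`window_gap_max` noise tokens between them (and equally bounded noise
prefix and suffix).

Two features of the noise model emulate real consultation text:

* **Topical pools.** The noise vocabulary is partitioned into
  per-subject pools and each sentence draws its noise from the pool of
  its subject. Real discourse about a subject reuses the vocabulary of
  that life domain; distributionally, these shared contexts are what
  allow *input-side* embeddings to place a subject near its actions at
  all. With a flat uniform noise vocabulary, a subject and its actions
  never share contexts (the subject's contexts are its actions and the
  action's contexts are its subjects), and analogy recovery sits at
  chance — a property worth knowing about template corpora generally.
* **Casual-verb confounders.** A small set of verbs
  (`n_casual_verbs = 10`) is attached to random subjects and inserted at
  a low rate (`casual_verb_rate = 0.015`) into the attached subject's
  sentences — verbs that habitually co-occur with a subject without
  constituting a negative life event (think `<mom:nags>`). They
  reproduce the rare-event pathology of pointwise mutual information:
  a low-frequency verb whose few occurrences all sit near one subject
  out-scores genuinely planted actions under PPMI, while barely-trained
  embedding vectors for the same verbs stay away from the analogy
  target. This is the mechanism by which embedding-based analogical
  inference overtakes raw PPMI induction on the benchmark, and it gives
  the notion of a subject with an *unambiguous* planted signal (no
  positive-PPMI verb candidate outside its planted set) concrete
  meaning.

Defaults — 5 categories x 2 subjects, 20 actions, density 0.5, 5,000
sentences, 100 noise tokens, gap 2 — are the package's benchmark
conditions and are exercised end-to-end by the test suite.

What the generator does *not* emulate: polysemy, morphology, multiple or
overlapping patterns per sentence, unplanted subject-action
co-occurrences, non-stationary topic drift, and the heavy-tailed
frequency distribution of natural vocabulary. Passing recovery tests on
this world therefore demonstrates that the pipeline's machinery is
correct and that its qualitative orderings can emerge from purely
distributional signal; it does not certify performance levels on real
psychiatric text.

## Numerical and design choices

* Vocabulary ids are contiguous integers `1..V` in decreasing frequency
  order (ties by first appearance); the id order is also the ranking
  tie-break.
* Unknown tokens occupy window positions (so distances are preserved)
  but never contribute to matrices, vectors or training.
* Embedding defaults: dimension 300, window 5, 5 negatives, 5 epochs,
  initial learning rate 0.025. The benchmark and tests train at
  dimension 32 for 30 epochs, which suffices on the synthetic world and
  keeps the suite fast; sensitivity sweeps cover dimensions and HAL
  windows through `sweep_parameter()`.
* Degenerate inputs: zero vectors score 0 with a warning under cosine;
  PPMI construction fails loudly on a corpus with no co-occurring pairs;
  an empty candidate set after filtering returns an empty ranking with a
  warning.
* All randomness (world generation, training initialization and negative
  sampling, partition sampling) flows from explicit integer seeds;
  identical seeds give byte-identical corpora, vector tables and
  reports.
* Problem sizes in the test suite: representation oracles run on corpora
  of 40-200 sentences; engine and metric oracles on at least 100 random
  instances each; the end-to-end benchmark uses the default synthetic
  world with a 40-queries-per-subset test sample (~850 queries). The
  full study-design combinatorics (152 x 54 grid, 132 seeds, 25 subsets,
  1,000/2,000-per-subset sampling) are reproduced exactly with a
  synthetic design matrix and a 49-expansion synonym map, which yields a
  pool of ~300,000 expanded queries.

## Known limitations

* The CBOW/skip-gram trainer is single-threaded and intended for
  corpora up to a few hundred thousand tokens; for web-scale corpora,
  train vectors externally and load them through the word2vec text
  format reader.
* HAL matrices are dense `|V| x |V|`; vocabularies beyond ~20,000 words
  will be memory-hungry.
* COSMUL's unshifted cosines depart from the shifted variant used in
  some analogy literature; scores are comparable within an engine, not
  across engines.
* PPMI induction ignores `alpha` and `beta` entirely, so its rankings
  are identical for all queries sharing an `alpha_star` — an intended
  property of the baseline, not a bug.
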