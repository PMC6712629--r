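# nlelp

Analogical reasoning for mining **negative-life-event language
patterns** (NLE-LPs) — `<subject:action>` pairs such as
`<parent:divorce>` or `<boyfriend:break_up>` — from tokenized text.
Automatically surfacing such patterns from consultation text helps
identify people who may need psychiatric care; this package provides the
full mining pipeline for researchers in clinical text mining: word
representations, analogy-based pattern inference, query-set
construction, and ranked-retrieval evaluation, plus a synthetic-corpus
generator with planted, recoverable structure for end-to-end
benchmarking.

## The method

Given a seed pattern `<α:β>` (e.g. `<older_brother:drop_out>`) and
another subject `α*`, the analogy query `<α:β>::<α*:?>` asks for actions
that stand to `α*` as `β` stands to `α`. Candidates are scored against
the analogy target

    λ = V(β) − V(α) + V(α*)

where `V(·)` is one of three word representations:

* **HAL-VEC** — rows of a hyperspace-analog-to-language matrix:
  windowed, distance-weighted co-occurrence counts (preceding window of
  `n` words, adjacent word weighted `n`, furthest weighted 1);
* **PPMI** — positive pointwise mutual information,
  `max(0, log p(x,y)/(p(x)p(y)))` over windowed co-occurrence;
* **CBOW / SG embeddings** — trained from scratch with negative
  sampling (compiled, deterministic under a seed), or loaded from
  word2vec text format.

Four inference engines rank candidate actions:

| engine   | score of candidate c |
|----------|----------------------|
| COSINE   | `cos(V(c), λ)` (3CosAdd) |
| COSMUL   | `cos(V(c),V(β)) · cos(V(c),V(α*)) / (cos(V(c),V(α)) + 0.001)` (3CosMul) |
| HAL-INF  | `Σ_{i∈QP(λ)∩QP(V(c))} V(c)_i / Σ_{j∈QP(λ)} λ_j`, `QP(v) = {k : v_k > mean(v)}` |
| PPMI     | `PPMI(α*, c)` (single-subject induction) |

Gold relevance comes from an annotated **logical-relationship matrix**
(actions × subjects, unanimous-consensus across annotators); queries are
grouped into 25 ordered category-pair subsets (5 within-category, 20
across-category over the five life domains family / love / school /
work / social) and scored with **prec@n** and **MRR**.

## Worked example

```r
library(nlelp)

world <- generate_synthetic_world(synthetic_world_spec(seed = 42))
world
#> <nlelp_world> 5000 sentences; 10 subjects x 20 actions, 100 planted pairs

vocab <- build_vocab(world$corpus)
cbow  <- train_embeddings(world$corpus, vocab,
                          embedding_config("cbow", dim = 32, epochs = 30, seed = 7))
ppmi  <- build_ppmi(world$corpus, vocab, w = 3)

queries   <- generate_queries(world$lr)
partition <- partition_queries(queries, per_subset_train = 0,
                               per_subset_test = 40, seed = 11)
partition
#> <query_partition> 25 subsets (5 within, 20 across); train 0, test 868

report <- run_experiment(partition, engines = c("cosine", "ppmi"),
                         representations = list(cbow = cbow, ppmi = ppmi),
                         filter = candidate_filter(world$pos))
report
#> <eval_report> within/across-category ranked-retrieval metrics
#>         method within.prec_at_5 within.prec_at_10 within.mrr across.prec_at_5
#>  cbow + cosine            0.896             0.752      0.950           0.9250
#>    ppmi + ppmi            0.790             0.863      0.635           0.8013
#>  across.prec_at_10 across.mrr evaluated skipped
#>             0.7724     0.9742       868       0
#>             0.8715     0.6593       868       0
```

Read: on this synthetic world, CBOW embeddings with additive-cosine
analogy inference put a correct (planted) action at rank 1 for almost
every query (MRR ≈ 0.95–0.97) and ~90% of their top-5 suggestions are
planted patterns, while raw PPMI induction — which ranks purely by
direct co-occurrence with `α*` — is regularly fooled at rank 1 by
casual verbs that habitually co-occur with a subject without being a
negative life event (MRR ≈ 0.64–0.66). A single query looks like this:

```r
q <- queries[1, ]
rank_candidates("cosine", cbow, q, filter = candidate_filter(world$pos), top_k = 5)
#> <ranked_result> engine cosine, <family_s02:act_001>::<family_s01:?>, 5 candidates
#>   1. act_018 (0.5211)
#>   2. act_002 (0.5142)
#>   3. act_003 (0.4819)
#>   4. act_005 (0.4390)
#>   5. act_006 (0.4340)
```

All five suggested actions are in the planted row of `family_s01`
(prec@5 = 1 for this query).

Every stage is also available from a shell through the thin CLI:

```sh
Rscript inst/cli/nlelp.R simulate --out run --sentences 5000 --seed 1
Rscript inst/cli/nlelp.R build-ppmi --corpus run/corpus.txt --out run/ppmi.tsv
Rscript inst/cli/nlelp.R make-queries --lr run/lr.tsv --out run/queries.tsv
Rscript inst/cli/nlelp.R infer --engine ppmi --matrix run/ppmi.tsv \
    --queries run/queries.tsv --lexicon run/pos.tsv --out run/ranked.tsv
Rscript inst/cli/nlelp.R evaluate --ranked run/ranked.tsv \
    --queries run/queries.tsv --lr run/lr.tsv --out run/report.json
```

## Package layout

* `R/corpus.R`, `R/synthetic.R` — corpus I/O, vocabulary, windows, the
  synthetic-world generator
* `R/hal.R`, `R/ppmi.R`, `R/embeddings.R` + `src/sgns.cpp`,
  `R/vectors-io.R` — the three word representations and vector I/O
* `R/lr-matrix.R`, `R/queries.R` — annotation aggregation, query
  generation/expansion/partitioning
* `R/engines.R` — the four inference engines and candidate filtering
* `R/evaluation.R` — metrics, experiments, sensitivity sweeps, reports
* `R/cli.R`, `inst/cli/nlelp.R` — command-line pipeline
* `vignettes/nle-pattern-mining.Rmd` — the methods vignette (model,
  assumptions, generator design, limitations)
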