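# adrscore

Embedding-similarity prediction of drug–side-effect relationships.

## What it does, and for whom

Labeled side-effect resources (SIDER-style tables of drug–MedDRA-term
pairs) are incomplete: many real adverse drug reactions are missing simply
because they were reported after the resource was curated. `adrscore` is
for pharmacovigilance and drug-safety researchers who have (a) such a
relation table and (b) embedding vectors for the drug and side-effect
terms — from any pretrained source in word2vec text format, or from a
pluggable encoder — and want a ranked list of plausible *unknown*
drug–side-effect pairs, with honest evaluation and external validation.

The core statistic is a dual leave-one-out nearest-neighbour score. With
binary adjacency `R` (drugs × side effects) and within-axis similarity
matrices `S_D`, `S_E` (cosine by default):

    sim_x(α, β) = max{ S_D[α, i] : R[i, β] = 1, i ≠ α }
    sim_y(α, β) = max{ S_E[β, j] : R[α, j] = 1, j ≠ β }
    score(α, β) = sim_x(α, β) × sim_y(α, β)

i.e. a pair scores highly when the drug is close to a drug already known
for the side effect *and* the side effect is close to a side effect
already known for the drug. The query entity is always excluded from its
own related set, so known pairs get no self-similarity credit. Around the
score the package provides ROC/AUC evaluation with a Youden-optimal
threshold, single-similarity ablations, balanced-resampling Fisher exact
validation against an external relation extract (FAERS-style), a
planted-factor synthetic benchmark, and a one-call pipeline.

## Worked example

Everything below runs offline on the built-in planted-factor benchmark
(60 drugs × 120 side effects, 6 latent factors shared by the relation
structure and the noisy embeddings):

```r
library(adrscore)

bench <- generate_benchmark(synthetic_config())
adj   <- build_adjacency(bench$relations)
adj
#> adr_adjacency: 60 drugs x 120 side effects, 847 known pairs

drug_sim <- pairwise_similarity(bench$drug_embeddings, "cosine")
se_sim   <- pairwise_similarity(bench$se_embeddings,   "cosine")
scores   <- score_all_pairs(adj, drug_sim, se_sim)

roc <- evaluate_scores(scores, adj)
roc
#> adr_roc: AUC 0.8507, optimal threshold 0.1194 (sensitivity 0.777,
#>          specificity 0.842), 847 pos / 6353 neg

recovery_auc(scores, bench)$auc   # recovery of the planted structure
#> [1] 0.9494651

head(top_novel_pairs(scores, adj, k = 5))
#>     drug    se     sim_x     sim_y     score
#> 1 drug41 se081 0.6447936 0.6281291 0.4050136
#> 2 drug04 se088 0.5549670 0.6281291 0.3485910
#> 3 drug14 se081 0.5549670 0.6281291 0.3485910
#> 4 drug05 se078 0.6447936 0.5233386 0.3374454
#> 5 drug13 se105 0.5480506 0.6112639 0.3350035

ext <- generate_external_extract(scores, enrichment = 8, n_pairs = 400, seed = 8)
val <- balanced_fisher_validation(predict_labels(scores, roc$optimal_threshold),
                                  ext, n_repeats = 500, seed = 8)
val
#> adr_validation: 500 repeats of 400 known vs 400 sampled unknown pairs
#>   mean OR 2.881 (median 2.898), mean p 3.49e-08 (median 8.84e-12)
```

Reading the numbers: the in-sample AUC of 0.85 says the score ranks known
pairs far above random among all 7200 cells; the recovery AUC of 0.95
says the ranking recovers the *planted* factor structure (the in-sample
AUC is capped below that because some generated relations are pure
cross-factor noise — see the methods vignette). The top novel pairs are
unknown cells whose drug and side effect both sit near known partners;
the validation odds ratio of ~2.9 (p ≪ 0.001) says pairs present in the
enriched "external" extract are about three times more likely to be
predicted related than sampled unknown pairs.

With real data, replace the generator with your own files:

```r
adj <- build_adjacency(read_relation_table("meddra_all_se.tsv"))
drug_emb <- load_word_vectors("drug_vectors.txt", adj$drug_vocab)
se_emb   <- load_word_vectors("se_vectors.txt",   adj$se_vocab)
```

or run everything at once with `run_pipeline(run_config(...))`, which
writes `scores.tsv`, `roc.json`, `validation.json` and `run.log` into an
output directory. A thin command-line wrapper with the same stages as
subcommands is in `inst/scripts/adrscore.R`.

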