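---
title: "Scoring drug–side-effect relationships from term embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug–side-effect relationships from term embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrscore)
```

## The problem and the model

Adverse drug reactions are a leading cause of hospitalization, and the
labeled side effects of marketed drugs (as curated in resources such as
SIDER, with MedDRA-coded event terms) are necessarily incomplete. adrscore
ranks *unknown* drug–side-effect pairs by how strongly the geometry of a
term-embedding space, anchored in the known relationships, suggests a
relationship.

The known relationships form a binary adjacency matrix $R$ with drugs as
rows and side effects as columns: $R_{ij} = 1$ exactly when the pair is
known. Each drug and each side-effect term also carries an embedding
vector (from any source: a word2vec-format text file, a contextual encoder
plugged in through `encode_terms()`, or the synthetic generator). Within
each axis the package computes a full pairwise similarity matrix; cosine
similarity
$$\cos(A,B) = \frac{A \cdot B}{\lVert A\rVert\,\lVert B\rVert}$$
is the default, with negated Euclidean and Manhattan distance, generalized
(Ruzicka) Jaccard and the raw dot product available for comparison.

The relation score of a query pair $(\mathrm{Drug}_\alpha,
\mathrm{SE}_\beta)$ combines two *leave-one-out maximum similarities*:

$$\mathrm{sim}_x = \max_{i \in \mathrm{Related}_{\mathrm{Drugs}}(\beta) \setminus \{\alpha\}} S^D_{\alpha i},
\qquad
\mathrm{sim}_y = \max_{j \in \mathrm{Related}_{\mathrm{SE}}(\alpha) \setminus \{\beta\}} S^E_{\beta j},
\qquad
\mathrm{score} = \mathrm{sim}_x \times \mathrm{sim}_y .$$

$\mathrm{Related}_{\mathrm{Drugs}}(\beta)$ is the set of drugs already
known for side effect $\beta$ (a column of $R$), and vice versa. The
exclusion of the query entity from its own related set is essential: for a
known pair it removes the trivial self-similarity evidence
($S_{\alpha\alpha} = 1$), which is what makes in-sample evaluation
meaningful at all. Both factors ask a nearest-neighbour question — "is
this drug close to any drug already implicated in this side effect, and is
this side effect close to any side effect already caused by this drug?" —
and the product requires both answers to be yes.

## Decisions the formulas leave open

Several points are underdetermined by the formulas above; the package
resolves them as follows, and each choice is visible in the API.

**Empty related sets.** A side effect known for exactly one drug, scored
against that drug, has an empty related set after exclusion (and
symmetrically for drugs with one known side effect). The factor is set to
0 — "no evidence", without inventing a prior — and the cell is flagged in
an explicit mask (`empty_x` / `empty_y`), so evaluation can either keep
such cells as score-0 entries (the default, which keeps the full
$|drugs| \times |SEs|$ pair count) or drop them (`drop_masked = TRUE`).

**Negative similarities.** Cosine factors are not clamped at 0. The
product of two negative factors is positive; this is documented rather
than hidden because clamping would silently change cross-metric
comparisons. With real biomedical term vectors negative cosines are rare.

**Distance metrics.** Euclidean and Manhattan distances become
similarities by negation. Any strictly decreasing transform yields the
same ranking, hence identical ROC curves and AUC; negation is chosen
because it is parameter-free. The consequence — worth remembering when
comparing metrics — is that the Youden threshold *value* is on the
negated-distance scale and is not comparable across metrics.

**Jaccard on dense vectors.** Set Jaccard is undefined for real-valued
embeddings. The package implements the generalized (Ruzicka) form
$\sum_i \min(a_i,b_i) / \sum_i \max(a_i,b_i)$, which requires nonnegative
components; negative components raise an error, and
`shift_nonnegative = TRUE` offers a documented min-shift instead of a
silent binarization threshold.

**Term normalization.** Terms are lowercased and trimmed on load, and
vocabularies are the lexicographically sorted unique terms, so all
matrices are reproducible across platforms. Full synonym resolution
(compound identifiers, MedDRA hierarchy) is upstream curation, not
reimplemented here; a two-column mapping file can merge known synonyms.

**Multi-token terms.** When an encoder backend is used, each term is
encoded independently as its own sequence and the final-layer token
vectors (special tokens excluded) are mean-pooled — the standard
context-free term-embedding choice, symmetric in token order within the
term; `first_token` pooling is available as an alternative, and only the
last hidden layer is exposed. Unknown-term policy for file-loaded vectors
defaults to `error`, because silently zeroed vectors corrupt cosine
rankings.

## Evaluation

`evaluate_scores()` labels all scored pairs against the same adjacency
used to build the related sets and computes one ROC curve — in-sample
evaluation that relies on the leave-one-out exclusion to avoid
self-evidence. This mirrors how the method is used in practice (all known
pairs inform the ranking of the unknown ones); `holdout_roc()` is provided
as the methodologically stricter alternative (mask a fraction of known
pairs, score with the rest, evaluate on the masked set).

The curve is built over every unique score value with a *strict*
exceedance rule (a pair is called related when its score is greater than
the threshold, matching `predict_labels()`), ties grouped into single
curve steps. AUC is computed two ways — trapezoidal area and the
tie-corrected Mann–Whitney rank statistic — which agree to numerical
precision; the rank form is stored as the authoritative value because it
is exact under heavy ties (score 0 is shared by every masked cell). The
operating threshold maximizes Youden's $J = \mathrm{TPR} - \mathrm{FPR}$,
taking the smallest qualifying threshold on ties (the most sensitive of
the equally good cut-offs).

`ablation_single_similarity()` ranks by `sim_x` alone, `sim_y` alone, or
the product, quantifying what each similarity axis contributes.

## External validation

`balanced_fisher_validation()` checks thresholded predictions against an
independently derived relation extract (in the motivating use case, pairs
observed in FAERS spontaneous reports). Because externally unknown pairs
vastly outnumber known ones, each repeat keeps all known pairs and samples
an equal number of unknown pairs without replacement, builds the 2×2
table of external status versus prediction, and computes a two-sided
Fisher exact p-value (`stats::fisher.test`) plus the cross-product odds
ratio $(ad)/(bc)$ with the Haldane–Anscombe +0.5 correction applied to
all cells when any cell is zero. Two-sidedness is the conservative
default. Repeats are aggregated by the arithmetic mean (the convention
this procedure is usually reported with); because means of p-values and of
skewed odds ratios are fragile summaries, the median of each is reported
alongside, clearly labeled. One seeded generator drives the repeats in
order, so a `(seed, n_repeats)` pair pins the result exactly.

## The synthetic benchmark

`generate_benchmark()` plants a latent factor structure behind both data
modalities: each drug and side effect draws one of $K$ factors uniformly;
a relation exists with probability $p_\mathrm{in}$ when factors match and
$p_\mathrm{out}$ otherwise; embeddings are the factor's orthonormal
centroid — a standard basis vector, so the zero-noise geometry is exactly
analyzable (within-factor cosine 1, cross-factor 0) — plus isotropic
Gaussian noise of standard deviation `noise_sd` per component. Terms left
isolated by the Bernoulli draw are redrawn until every drug and side
effect has at least one relation, matching the invariant that
vocabularies induced from a relation table have no empty rows or columns.

The defaults — 60 drugs × 120 side effects, $K = 6$, dimension 32,
$p_\mathrm{in} = 0.6$, $p_\mathrm{out} = 0.02$, `noise_sd` 0.3, seed 7 —
are the study conditions used throughout the test suite: large enough
that AUCs are stable to a few hundredths, small enough that the whole
suite runs in seconds. The p_in = p_out null checks in the tests use
200 × 400 at relation probability 0.05, ten replicates, which keeps the
Monte-Carlo error of the mean AUC well under the 0.05 band being
asserted.

Two evaluations must not be conflated on this benchmark:

* the **pipeline AUC** (`evaluate_scores()`), against the generated
  relation table — the method's own evaluation; and
* the **recovery AUC** (`recovery_auc()`), against the planted
  factor-match ground truth — the benchmark's success metric.

The pipeline AUC is bounded away from 1 *by construction* at these
defaults: the $p_\mathrm{out}$ relations are cross-factor pairs labeled
positive that carry no geometric signal (about 14% of positives at the
defaults), and after leave-one-out exclusion the known and unknown
within-factor pairs are statistically exchangeable, so the within-factor
negatives tie with the bulk of the positives. Working through those two
terms gives a ceiling near 0.89 even at zero noise; the measured value at
the defaults is about 0.85. The recovery AUC has no such ceiling (about
0.95 at the defaults, exactly 1 at zero noise with $p_\mathrm{out} = 0$)
and is the quantity that should be read as "did the pipeline recover the
planted structure". The tests assert recovery ≥ 0.90 at the defaults,
monotone degradation over a noise sweep, and chance-level recovery when
$p_\mathrm{in} = p_\mathrm{out}$.

`generate_external_extract()` emulates an enriched external source:
cells are sampled with probability proportional to
$\mathrm{enrichment}^{q}$, where $q$ is the score's rank quantile, so
enrichment 1 is the exact null (uniform sampling, mean odds ratio 1) and
larger values concentrate the "external" pairs on high-scoring cells.

What the generator does *not* emulate: term morphology and synonymy,
the heavy-tailed degree distributions of real pharmacovigilance data,
reporting biases, and embeddings whose similarity structure reflects
anything other than a clean factor geometry. Passing the synthetic tests
therefore demonstrates the correctness and statistical behaviour of the
machinery, not the clinical performance of any particular embedding
model.

## A worked toy example

```{r}
rel <- relation_table(c("a", "b"), c("x", "y"))
adj <- build_adjacency(rel)
adj$R
```

With drug similarity 0.8 and side-effect similarity 0.5 between the two
terms of each axis, the unknown pair (a, y) gets
$\mathrm{sim}_x = 0.8$ (drug b is known for y), $\mathrm{sim}_y = 0.5$
(side effect x is known for a), score $0.8 \times 0.5 = 0.4$ — while the
known pairs (a, x) and (b, y) have empty related sets after exclusion and
are masked to 0.

## Numerical and reproducibility notes

* All maxima are computed with `-Inf` sentinels for excluded entries, so
  masks are exact, not threshold-based.
* Cosine values are clipped to $[-1, 1]$ to absorb floating-point
  overshoot before any downstream comparison.
* Ranking ties in `top_novel_pairs()` break lexicographically by
  (drug, side effect), making reported candidate lists deterministic.
* Every stochastic stage (generator, held-out mask, external sampling,
  validation resampling) takes an explicit integer seed;
  `run_pipeline()` derives per-stage seeds from one master seed and logs
  them, and a rerun with the same configuration is byte-identical.

## Limitations

The scoring method inherits the limits of its inputs: it cannot rank a
drug or side effect absent from the relation table (no row/column), its
factors are only as meaningful as the embedding geometry, and in-sample
AUC — while protected from self-evidence by the leave-one-out rule —
still shares information between related sets and labels; use
`holdout_roc()` when an unbiased generalization estimate is needed.
Population-level scores say nothing about idiosyncratic, patient-specific
reactions, and candidates produced by `top_novel_pairs()` are hypotheses
for pharmacovigilance follow-up, not clinical findings.
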