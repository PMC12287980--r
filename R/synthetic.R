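#' Configuration for the planted-factor benchmark generator
#'
#' The generator plants a shared latent factor structure behind both the
#' relation table and the embeddings: each drug and each side effect is
#' assigned one of `n_factors` latent factors; a relation between a drug and
#' a side effect exists with probability `p_in` when their factors match and
#' `p_out` otherwise; each term's embedding is its factor's orthonormal
#' centroid (a standard basis vector in `dim` dimensions) plus isotropic
#' Gaussian noise of standard deviation `noise_sd`. Defaults are the study
#' conditions used throughout the test suite: 60 drugs x 120 side effects,
#' 6 factors, dimension 32, p_in 0.6, p_out 0.02, noise_sd 0.3, seed 7.
#'
#' @param n_drugs,n_ses Axis sizes.
#' @param n_factors Number of latent factors (at most `min(n_drugs, n_ses)`;
#'   at most `dim`).
#' @param dim Embedding dimension.
#' @param p_in,p_out Within- and cross-factor relation probabilities; a
#'   signal-bearing configuration has `p_in > p_out` (equality is allowed
#'   and yields a null structure).
#' @param noise_sd Embedding noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return An `adr_synth_config` list.
#' @export
synthetic_config <- function(n_drugs = 60L, n_ses = 120L, n_factors = 6L,
                             dim = 32L, p_in = 0.6, p_out = 0.02,
                             noise_sd = 0.3, seed = 7L) {
  stopifnot(n_drugs >= 1L, n_ses >= 1L, n_factors >= 1L,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1, noise_sd >= 0)
  if (n_factors > min(n_drugs, n_ses)) {
    stop("n_factors must not exceed min(n_drugs, n_ses)")
  }
  if (dim < n_factors) stop("dim must be at least n_factors")
  if (p_in < p_out) stop("p_in must be >= p_out (p_in > p_out for signal)")
  structure(list(n_drugs = as.integer(n_drugs), n_ses = as.integer(n_ses),
                 n_factors = as.integer(n_factors), dim = as.integer(dim),
                 p_in = p_in, p_out = p_out, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "adr_synth_config")
}

synth_terms <- function(prefix, n) {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate a planted-factor benchmark instance
#'
#' Draws factor assignments, the Bernoulli relation structure and the noisy
#' factor-centroid embeddings described in [synthetic_config()]. Drugs or
#' side effects left without any relation are redrawn until every term has
#' at least one (matching the invariant that vocabularies induced from a
#' relation table have no empty rows or columns); the number of redraws is
#' recorded. Term names are zero-padded (`drug01`, `se001`, ...) so
#' lexicographic vocabulary order equals generation order. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg An `adr_synth_config`.
#' @return List with `relations` (an `adr_relations`), `drug_embeddings`,
#'   `se_embeddings` (both `adr_embeddings`), `drug_factors`, `se_factors`
#'   (named integer vectors: ground truth), `n_resampled`, `config`.
#' @export
generate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "adr_synth_config"))
  set.seed(cfg$seed)
  nD <- cfg$n_drugs; nS <- cfg$n_ses; K <- cfg$n_factors
  drug_terms <- synth_terms("drug", nD)
  se_terms <- synth_terms("se", nS)
  drug_f <- sample.int(K, nD, replace = TRUE)
  se_f <- sample.int(K, nS, replace = TRUE)
  P <- matrix(cfg$p_out, nD, nS)
  P[outer(drug_f, se_f, "==")] <- cfg$p_in
  draw <- function(p) matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
  R <- draw(P)
  n_resampled <- 0L
  for (iter in seq_len(10000L)) {
    empty_rows <- which(rowSums(R) == 0L)
    empty_cols <- which(colSums(R) == 0L)
    if (length(empty_rows) == 0L && length(empty_cols) == 0L) break
    for (i in empty_rows) R[i, ] <- stats::rbinom(nS, 1L, P[i, ])
    for (j in empty_cols) R[, j] <- stats::rbinom(nD, 1L, P[, j])
    n_resampled <- n_resampled + length(empty_rows) + length(empty_cols)
    if (iter == 10000L) stop("could not populate all rows/columns; raise p_out")
  }
  ones <- which(R == 1L)
  ij <- arrayInd(ones, dim(R))
  rel <- relation_table(drug_terms[ij[, 1L]], se_terms[ij[, 2L]],
                        source_label = "synthetic planted-factor",
                        normalize = FALSE)
  centroids <- diag(cfg$dim)[, seq_len(K), drop = FALSE]
  noisy <- function(f, terms) {
    V <- t(centroids[, f, drop = FALSE]) +
      matrix(stats::rnorm(length(f) * cfg$dim, sd = cfg$noise_sd),
             length(f), cfg$dim)
    rownames(V) <- terms
    V
  }
  d_emb <- embedding_set(noisy(drug_f, drug_terms), "drug",
                         backend_label = "synthetic")
  s_emb <- embedding_set(noisy(se_f, se_terms), "side_effect",
                         backend_label = "synthetic")
  list(relations = rel,
       drug_embeddings = d_emb, se_embeddings = s_emb,
       drug_factors = stats::setNames(drug_f, drug_terms),
       se_factors = stats::setNames(se_f, se_terms),
       n_resampled = n_resampled, config = cfg)
}

#' Generate a synthetic external relation extract
#'
#' Emulates an external pharmacovigilance extract whose reported pairs are
#' enriched for genuinely related (high-scoring) cells: cells are sampled
#' without replacement with probability proportional to
#' `enrichment ^ q`, where `q` in \[0, 1\] is the score's rank quantile
#' (1 = highest score). `enrichment = 1` gives uniform sampling — the null
#' extract with no association to the scores.
#'
#' @param scores An `adr_scores` giving the sampling frame and ranks.
#' @param enrichment Enrichment strength (>= 1).
#' @param n_pairs Number of external pairs to draw (at most the number of
#'   cells).
#' @param seed Integer RNG seed.
#' @return An `adr_relations` labeled `"synthetic external"`.
#' @export
generate_external_extract <- function(scores, enrichment = 1, n_pairs, seed = 1L) {
  stopifnot(inherits(scores, "adr_scores"), enrichment >= 1, n_pairs >= 1L)
  n_cells <- length(scores$score)
  if (n_pairs > n_cells) stop("n_pairs exceeds the number of cells")
  q <- rank(as.vector(scores$score), ties.method = "average") / n_cells
  set.seed(seed)
  cells <- sample.int(n_cells, n_pairs, prob = enrichment^q)
  ij <- arrayInd(cells, dim(scores$score))
  relation_table(scores$drug_vocab$terms[ij[, 1L]],
                 scores$se_vocab$terms[ij[, 2L]],
                 source_label = "synthetic external", normalize = FALSE)
}

#' Planted-structure recovery AUC
#'
#' The benchmark's success metric: how well the relation-score ranking
#' recovers the planted factor structure, measured as the AUC of the scores
#' against factor-match ground truth (label 1 when drug and side effect
#' share a latent factor). This is distinct from the pipeline's own
#' evaluation against the known adjacency ([evaluate_scores()]), which is
#' bounded away from 1 by construction: cross-factor relations drawn with
#' probability `p_out` are labeled positive but score low, and after
#' leave-one-out exclusion the known and unknown within-factor pairs are
#' exchangeable.
#'
#' @param scores An `adr_scores` computed on a benchmark instance.
#' @param benchmark The [generate_benchmark()] result the scores came from.
#' @param unknown_only Restrict to pairs absent from the benchmark relation
#'   table (requires `adj`).
#' @param adj The `adr_adjacency`, needed when `unknown_only = TRUE`.
#' @return An `adr_roc` over the factor-match labels.
#' @export
recovery_auc <- function(scores, benchmark, unknown_only = FALSE, adj = NULL) {
  dterms <- scores$drug_vocab$terms
  sterms <- scores$se_vocab$terms
  truth <- outer(benchmark$drug_factors[dterms], benchmark$se_factors[sterms],
                 "==") * 1L
  if (unknown_only) {
    if (is.null(adj)) stop("unknown_only = TRUE requires adj")
    keep <- adj$R == 0L
    return(roc_auc(scores$score[keep], truth[keep]))
  }
  roc_auc(as.vector(scores$score), as.vector(truth))
}
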