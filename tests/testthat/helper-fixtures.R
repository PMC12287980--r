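# Shared fixtures and independent brute-force oracles.

# 2x2 toy used across the scoring examples: R = I, drug similarities 0.8,
# side-effect similarities 0.5 off-diagonal.
toy_instance <- function() {
  rel <- relation_table(c("a", "b"), c("x", "y"))
  adj <- build_adjacency(rel)
  drug_sim <- structure(list(axis = "drug", metric = "cosine",
                             S = matrix(c(1, .8, .8, 1), 2,
                                        dimnames = list(c("a", "b"), c("a", "b"))),
                             higher_is_closer = TRUE), class = "adr_similarity")
  se_sim <- structure(list(axis = "side_effect", metric = "cosine",
                           S = matrix(c(1, .5, .5, 1), 2,
                                      dimnames = list(c("x", "y"), c("x", "y"))),
                           higher_is_closer = TRUE), class = "adr_similarity")
  list(adj = adj, drug_sim = drug_sim, se_sim = se_sim)
}

# Hand-built adjacency over arbitrary 0/1 matrices (bypasses relation-table
# induction so empty rows/columns are possible).
manual_adjacency <- function(R) {
  rownames(R) <- sprintf("d%02d", seq_len(nrow(R)))
  colnames(R) <- sprintf("s%02d", seq_len(ncol(R)))
  storage.mode(R) <- "integer"
  structure(list(R = R,
                 drug_vocab = vocabulary(rownames(R), "drug", normalize = FALSE),
                 se_vocab = vocabulary(colnames(R), "side_effect",
                                       normalize = FALSE)),
            class = "adr_adjacency")
}

manual_similarity <- function(S, axis) {
  n <- nrow(S)
  pre <- if (axis == "drug") "d%02d" else "s%02d"
  dimnames(S) <- list(sprintf(pre, seq_len(n)), sprintf(pre, seq_len(n)))
  structure(list(axis = axis, metric = "cosine", S = S,
                 higher_is_closer = TRUE), class = "adr_similarity")
}

random_symmetric <- function(n) {
  M <- matrix(stats::runif(n * n, -1, 1), n)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  S
}

# Brute-force scoring oracle: explicit loops over every pair and every
# member of its related set, straight from the definitions.
naive_score_all <- function(adj, drug_sim, se_sim) {
  R <- adj$R
  nD <- nrow(R); nS <- ncol(R)
  sx <- matrix(0, nD, nS); sy <- matrix(0, nD, nS)
  ex <- matrix(FALSE, nD, nS); ey <- matrix(FALSE, nD, nS)
  for (a in seq_len(nD)) {
    for (b in seq_len(nS)) {
      best <- -Inf
      for (i in seq_len(nD)) {
        if (R[i, b] == 1L && i != a && drug_sim$S[a, i] > best) {
          best <- drug_sim$S[a, i]
        }
      }
      if (is.finite(best)) sx[a, b] <- best else ex[a, b] <- TRUE
      best <- -Inf
      for (j in seq_len(nS)) {
        if (R[a, j] == 1L && j != b && se_sim$S[b, j] > best) {
          best <- se_sim$S[b, j]
        }
      }
      if (is.finite(best)) sy[a, b] <- best else ey[a, b] <- TRUE
    }
  }
  score <- sx * sy
  score[ex | ey] <- 0
  list(score = score, sim_x = sx, sim_y = sy, empty_x = ex, empty_y = ey)
}

# Pairwise-enumeration AUC oracle: concordant pos-neg pairs, half credit
# for ties.
naive_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

scored_benchmark <- function(cfg = synthetic_config(), metric = "cosine") {
  bench <- generate_benchmark(cfg)
  adj <- build_adjacency(bench$relations)
  list(bench = bench, adj = adj,
       drug_sim = pairwise_similarity(bench$drug_embeddings, metric),
       se_sim = pairwise_similarity(bench$se_embeddings, metric))
}
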