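test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_factors = 10L, n_drugs = 5L, n_ses = 50L),
               "n_factors")
  expect_error(synthetic_config(dim = 4L, n_factors = 6L), "dim")
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.5), "p_in")
  expect_s3_class(synthetic_config(p_in = 0.2, p_out = 0.2), "adr_synth_config")
})

test_that("generation is deterministic given the seed", {
  b1 <- generate_benchmark(synthetic_config(seed = 99L))
  b2 <- generate_benchmark(synthetic_config(seed = 99L))
  expect_identical(b1$relations$pairs, b2$relations$pairs)
  expect_identical(b1$drug_embeddings$vectors, b2$drug_embeddings$vectors)
  b3 <- generate_benchmark(synthetic_config(seed = 100L))
  expect_false(identical(b1$relations$pairs, b3$relations$pairs))
})

test_that("zero noise gives exact within/cross-factor cosine geometry", {
  b <- generate_benchmark(synthetic_config(n_drugs = 20L, n_ses = 30L,
                                           n_factors = 4L, dim = 8L,
                                           noise_sd = 0, seed = 2L))
  S <- pairwise_similarity(b$drug_embeddings, "cosine")$S
  same <- outer(b$drug_factors, b$drug_factors, "==")
  expect_true(all(S[same] == 1))
  expect_true(all(S[!same] == 0))
})

test_that("relation counts match the closed-form expectation", {
  cfg <- synthetic_config()
  b <- generate_benchmark(cfg)
  n_obs <- nrow(b$relations$pairs)
  K <- cfg$n_factors
  p_bar <- cfg$p_in / K + cfg$p_out * (1 - 1 / K)
  expected <- cfg$n_drugs * cfg$n_ses * p_bar
  sd_bin <- sqrt(cfg$n_drugs * cfg$n_ses * p_bar * (1 - p_bar))
  expect_lt(abs(n_obs - expected), 3 * sd_bin)
})

test_that("every generated drug and side effect has at least one relation", {
  # sparse enough that isolated terms occur and must be resampled
  b <- generate_benchmark(synthetic_config(n_drugs = 40L, n_ses = 60L,
                                           n_factors = 4L, dim = 8L,
                                           p_in = 0.15, p_out = 0.01,
                                           seed = 17L))
  adj <- build_adjacency(b$relations)
  expect_equal(dim(adj), c(40L, 60L))
  expect_true(all(rowSums(adj$R) >= 1))
  expect_true(all(colSums(adj$R) >= 1))
  expect_gte(b$n_resampled, 1L)
})

test_that("at zero noise and p_out 0, within-factor pairs dominate the ranking", {
  b <- generate_benchmark(synthetic_config(n_drugs = 12L, n_ses = 18L,
                                           n_factors = 3L, dim = 4L,
                                           p_in = 0.7, p_out = 0,
                                           noise_sd = 0, seed = 4L))
  adj <- build_adjacency(b$relations)
  sc <- score_all_pairs(adj,
                        pairwise_similarity(b$drug_embeddings),
                        pairwise_similarity(b$se_embeddings))
  truth <- outer(b$drug_factors[rownames(adj$R)],
                 b$se_factors[colnames(adj$R)], "==")
  unknown <- adj$R == 0L
  within_unknown <- sc$score[unknown & truth]
  cross <- sc$score[unknown & !truth]
  expect_gt(min(within_unknown), max(cross))
  r <- recovery_auc(sc, b, unknown_only = TRUE, adj = adj)
  expect_equal(r$auc, 1)
})

test_that("synthetic output flows through the same files the real pipeline reads", {
  b <- generate_benchmark(synthetic_config(n_drugs = 10L, n_ses = 15L,
                                           n_factors = 2L, dim = 4L, seed = 8L))
  dir <- withr::local_tempdir()
  rel_path <- file.path(dir, "relations.tsv")
  utils::write.table(b$relations$pairs, rel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  vec_path <- file.path(dir, "drug.vec")
  write_word_vectors(b$drug_embeddings, vec_path)
  adj <- build_adjacency(read_relation_table(rel_path))
  emb <- suppressMessages(load_word_vectors(vec_path, adj$drug_vocab))
  expect_equal(dim(adj), c(10L, 15L))
  expect_equal(emb$vectors, b$drug_embeddings$vectors, tolerance = 1e-6)
})

test_that("external extract sampling is null at enrichment 1, skewed above it", {
  inst <- scored_benchmark(synthetic_config(n_drugs = 30L, n_ses = 50L,
                                            n_factors = 5L, dim = 8L, seed = 6L))
  sc <- score_all_pairs(inst$adj, inst$drug_sim, inst$se_sim)
  q <- rank(as.vector(sc$score)) / length(sc$score)
  cell_q <- function(ext) {
    idx <- (match(ext$pairs$se, colnames(inst$adj$R)) - 1L) * nrow(inst$adj$R) +
      match(ext$pairs$drug, rownames(inst$adj$R))
    mean(q[idx])
  }
  null_q <- cell_q(generate_external_extract(sc, 1, n_pairs = 300, seed = 3))
  rich_q <- cell_q(generate_external_extract(sc, 20, n_pairs = 300, seed = 3))
  expect_lt(abs(null_q - 0.5), 0.06)   # uniform sampling of rank quantiles
  expect_gt(rich_q, 0.65)
  expect_error(generate_external_extract(sc, 1, n_pairs = 1e6), "exceeds")
})

test_that("monotone external enrichment drives monotone odds ratios", {
  inst <- scored_benchmark(synthetic_config(n_drugs = 30L, n_ses = 50L,
                                            n_factors = 5L, dim = 8L, seed = 6L))
  sc <- score_all_pairs(inst$adj, inst$drug_sim, inst$se_sim)
  roc <- evaluate_scores(sc, inst$adj)
  preds <- predict_labels(sc, roc$optimal_threshold)
  ors <- vapply(c(1, 6, 30), function(enr) {
    ext <- generate_external_extract(sc, enr, n_pairs = 250, seed = 5)
    balanced_fisher_validation(preds, ext, n_repeats = 60, seed = 7)$mean_or
  }, 0)
  expect_gt(ors[2], ors[1])
  expect_gt(ors[3], ors[2])
  expect_gt(ors[3], 1)
})
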