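test_that("sim_x and sim_y follow the leave-one-out max definitions", {
  toy <- toy_instance()
  expect_equal(as.numeric(sim_x(toy$adj, toy$drug_sim, 1L, 2L)), 0.8)
  v <- sim_x(toy$adj, toy$drug_sim, 1L, 1L)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "empty"))
  expect_equal(as.numeric(sim_y(toy$adj, toy$se_sim, 1L, 2L)), 0.5)
  w <- sim_y(toy$adj, toy$se_sim, 1L, 1L)  # only known SE of drug a is x itself
  expect_true(attr(w, "empty"))

  # max over a 3-drug related set
  adj <- manual_adjacency(matrix(c(1, 1, 1, 0, 0, 0, 0, 0), 4, 2))
  S <- manual_similarity(diag(4), "drug")
  S$S[4, 1:3] <- S$S[1:3, 4] <- c(.2, .9, .4)
  expect_equal(as.numeric(sim_x(adj, S, 4L, 1L)), 0.9)

  expect_error(sim_x(toy$adj, toy$se_sim, 1L, 1L), "axis")
  expect_error(sim_y(toy$adj, toy$drug_sim, 1L, 1L), "axis")
})

test_that("relation score is the plain product of the two factors", {
  expect_equal(round(relation_score(0.861, 0.857), 3), 0.738)
  expect_equal(relation_score(0, 123), 0)
  expect_equal(relation_score(c(.5, -.5), c(.5, -.5)), c(.25, .25))
})

test_that("score_all_pairs matches the toy enumeration and flags empties", {
  toy <- toy_instance()
  sc <- score_all_pairs(toy$adj, toy$drug_sim, toy$se_sim)
  expect_equal(sc$score["a", "y"], 0.8 * 0.5)
  expect_equal(sc$score["b", "x"], 0.8 * 0.5)
  # known pairs empty out after exclusion in this minimal toy
  expect_true(all(diag(sc$empty_x)))
  expect_equal(unname(diag(sc$score)), c(0, 0))

  # all-ones adjacency: every related set survives exclusion
  adj <- manual_adjacency(matrix(1L, 3, 4))
  sc2 <- score_all_pairs(adj, manual_similarity(random_symmetric(3), "drug"),
                         manual_similarity(random_symmetric(4), "side_effect"))
  expect_false(any(sc2$empty_x | sc2$empty_y))
  expect_equal(n_scored_pairs(sc2), 12)

  mismatched <- manual_similarity(random_symmetric(5), "drug")
  expect_error(score_all_pairs(adj, mismatched,
                               manual_similarity(random_symmetric(4), "side_effect")),
               "vocabulary")
})

test_that("vectorized scoring equals the quadruple-loop oracle", {
  set.seed(101)
  for (rep in 1:8) {
    nD <- sample(3:12, 1); nS <- sample(3:15, 1)
    adj <- manual_adjacency(matrix(rbinom(nD * nS, 1, runif(1, .1, .6)), nD, nS))
    ds <- manual_similarity(random_symmetric(nD), "drug")
    ss <- manual_similarity(random_symmetric(nS), "side_effect")
    got <- score_all_pairs(adj, ds, ss)
    ref <- naive_score_all(adj, ds, ss)
    expect_equal(unname(got$score), ref$score, tolerance = 1e-12)
    expect_equal(unname(got$sim_x), ref$sim_x, tolerance = 1e-12)
    expect_equal(unname(got$sim_y), ref$sim_y, tolerance = 1e-12)
    expect_equal(unname(got$empty_x), ref$empty_x)
    expect_equal(unname(got$empty_y), ref$empty_y)
  }
})

test_that("unknowing a known pair changes nothing (exclusion already did)", {
  set.seed(7)
  inst <- scored_benchmark(synthetic_config(n_drugs = 15L, n_ses = 25L,
                                            n_factors = 3L, dim = 8L,
                                            p_in = 0.5, p_out = 0.1, seed = 21L))
  sc <- score_all_pairs(inst$adj, inst$drug_sim, inst$se_sim)
  known <- which(inst$adj$R == 1L, arr.ind = TRUE)
  for (r in sample(nrow(known), 5)) {
    a <- known[r, 1]; b <- known[r, 2]
    adj2 <- inst$adj
    adj2$R[a, b] <- 0L
    sc2 <- score_all_pairs(adj2, inst$drug_sim, inst$se_sim)
    expect_identical(sc2$score[a, b], sc$score[a, b])
    expect_identical(sc2$sim_x[a, b], sc$sim_x[a, b])
    expect_identical(sc2$sim_y[a, b], sc$sim_y[a, b])
  }
})

test_that("raising a similarity used in a max cannot lower the score", {
  set.seed(9)
  # drugs 1-3 related to SE 3; drug 5 is the query
  R <- matrix(0L, 5, 6)
  R[1:3, 3] <- 1L; R[cbind(1:5, c(1, 2, 4, 5, 6))] <- 1L
  adj <- manual_adjacency(R)
  ds <- manual_similarity(random_symmetric(5) * 0.3 + 0.5, "drug")
  ss <- manual_similarity(random_symmetric(6) * 0.3 + 0.5, "side_effect")
  base <- score_all_pairs(adj, ds, ss)
  ds2 <- ds
  ds2$S[5, 2] <- ds2$S[2, 5] <- 1  # drug 2 is in SE 3's related set
  bumped <- score_all_pairs(adj, ds2, ss)
  expect_gte(bumped$sim_x[5, 3], base$sim_x[5, 3])
  expect_equal(bumped$sim_x[5, 3], 1)
  expect_gte(bumped$score[5, 3], base$score[5, 3])
})

test_that("cosine-based scores stay in [-1, 1] and masked cells are 0", {
  inst <- scored_benchmark(synthetic_config(n_drugs = 20L, n_ses = 30L,
                                            n_factors = 4L, dim = 8L, seed = 3L))
  sc <- score_all_pairs(inst$adj, inst$drug_sim, inst$se_sim)
  expect_true(all(sc$sim_x >= -1 & sc$sim_x <= 1))
  expect_true(all(sc$sim_y >= -1 & sc$sim_y <= 1))
  expect_true(all(sc$score >= -1 & sc$score <= 1))
  masked <- sc$empty_x | sc$empty_y
  if (any(masked)) expect_true(all(sc$score[masked] == 0))
})

test_that("novel-pair ranking is deterministic, clamped and excludes knowns", {
  toy <- toy_instance()
  sc <- score_all_pairs(toy$adj, toy$drug_sim, toy$se_sim)
  top <- top_novel_pairs(sc, toy$adj, k = 10L)
  expect_equal(nrow(top), 2L)  # clamped to the unknown pairs
  expect_true(all(paste(top$drug, top$se) %in% c("a y", "b x")))
  expect_equal(top$score, sort(top$score, decreasing = TRUE))
  # equal scores here: lexicographic tie-break
  expect_equal(top$drug, c("a", "b"))

  adj <- manual_adjacency(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3))
  ds <- manual_similarity(random_symmetric(3), "drug")
  ss <- manual_similarity(random_symmetric(3), "side_effect")
  sc3 <- score_all_pairs(adj, ds, ss)
  top3 <- top_novel_pairs(sc3, adj, k = 3L)
  unknown <- which(adj$R == 0L)
  ref <- sort(sc3$score[unknown], decreasing = TRUE)
  expect_equal(top3$score, ref[seq_len(nrow(top3))])
  expect_true(all(adj$R[cbind(match(top3$drug, rownames(adj$R)),
                              match(top3$se, colnames(adj$R)))] == 0L))
})

test_that("long-format score export carries factors, labels and masks", {
  toy <- toy_instance()
  sc <- score_all_pairs(toy$adj, toy$drug_sim, toy$se_sim)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, toy$adj, f)
  df <- utils::read.delim(f)
  expect_equal(nrow(df), 4L)
  expect_equal(sum(df$known), 2L)
  row <- df[df$drug == "a" & df$se == "y", ]
  expect_equal(row$score, 0.4)
  expect_equal(row$sim_x, 0.8)
  expect_equal(row$masked, 0L)
})
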