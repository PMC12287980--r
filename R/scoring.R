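check_axis <- function(sim, axis) {
  if (sim$axis != axis) {
    stop("similarity matrix has axis '", sim$axis, "', expected '", axis, "'")
  }
}

check_vocab_match <- function(sim, terms, axis) {
  if (!identical(rownames(sim$S), terms)) {
    stop(axis, " similarity matrix vocabulary does not match the adjacency")
  }
}

# Row-wise maximum of a matrix with >= 0 columns; -Inf rows mean "no
# candidate left".
row_max <- function(M, n) {
  if (ncol(M) == 0L) return(rep(-Inf, n))
  do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

#' Leave-one-out drug-side similarity factor (sim_x)
#'
#' The maximum similarity of the query drug to the drugs known to be
#' associated with the query side effect, excluding the query drug itself
#' from its own related set. When the set is empty after exclusion (a side
#' effect known for only that one drug), the value is 0 and the `empty`
#' attribute is set: 0 encodes "no evidence" without inventing a prior, and
#' the flag keeps such cells auditable downstream.
#'
#' @param adj An `adr_adjacency`.
#' @param drug_sim Drug-axis `adr_similarity`.
#' @param drug,se Query terms or 1-based indices.
#' @return Scalar similarity, with logical attribute `empty`.
#' @export
sim_x <- function(adj, drug_sim, drug, se) {
  check_axis(drug_sim, "drug")
  check_vocab_match(drug_sim, rownames(adj$R), "drug")
  a <- resolve_index(drug, nrow(adj$R), adj$drug_vocab, "drug")
  rel <- setdiff(unname(related_drugs(adj, se)), a)
  if (length(rel) == 0L) return(structure(0, empty = TRUE))
  structure(max(drug_sim$S[a, rel]), empty = FALSE)
}

#' Leave-one-out side-effect similarity factor (sim_y)
#'
#' Mirror of [sim_x()]: the maximum similarity of the query side effect to
#' the side effects known for the query drug, excluding the query side
#' effect itself.
#'
#' @inheritParams sim_x
#' @param se_sim Side-effect-axis `adr_similarity`.
#' @return Scalar similarity, with logical attribute `empty`.
#' @export
sim_y <- function(adj, se_sim, drug, se) {
  check_axis(se_sim, "side_effect")
  check_vocab_match(se_sim, colnames(adj$R), "side effect")
  b <- resolve_index(se, ncol(adj$R), adj$se_vocab, "side effect")
  rel <- setdiff(unname(related_side_effects(adj, drug)), b)
  if (length(rel) == 0L) return(structure(0, empty = TRUE))
  structure(max(se_sim$S[b, rel]), empty = FALSE)
}

#' Relation score from the two similarity factors
#'
#' The relation score of a drug-side-effect pair is the product of its two
#' leave-one-out similarity factors. Negative cosine factors are not
#' clamped, so the product of two negatives can be positive; with real
#' biomedical term vectors negative cosines are rare, and clamping would
#' silently change metric comparisons.
#'
#' @param sim_x_val,sim_y_val Numeric (vectorized).
#' @return `sim_x_val * sim_y_val`.
#' @export
relation_score <- function(sim_x_val, sim_y_val) {
  as.numeric(sim_x_val) * as.numeric(sim_y_val)
}

#' Score every drug-side-effect pair
#'
#' Vectorized computation of `sim_x`, `sim_y` and their product for all
#' |drugs| x |side effects| cells, with leave-one-out exclusion of the query
#' entity from its own related set. Cells whose related set is empty after
#' exclusion carry factor 0 and are flagged in the corresponding mask.
#'
#' @param adj An `adr_adjacency`.
#' @param drug_sim,se_sim `adr_similarity` matrices over the adjacency
#'   vocabularies.
#' @return An `adr_scores` object: list of matrices `score`, `sim_x`,
#'   `sim_y`, logical `empty_x`, `empty_y`, plus the vocabularies.
#' @export
score_all_pairs <- function(adj, drug_sim, se_sim) {
  check_axis(drug_sim, "drug"); check_axis(se_sim, "side_effect")
  check_vocab_match(drug_sim, rownames(adj$R), "drug")
  check_vocab_match(se_sim, colnames(adj$R), "side effect")
  R <- adj$R
  nD <- nrow(R); nS <- ncol(R)
  SX <- matrix(0, nD, nS, dimnames = dimnames(R))
  SY <- matrix(0, nD, nS, dimnames = dimnames(R))

  # sim_x: per side effect, max similarity of each drug to that side
  # effect's related drugs, self-similarity masked out.
  for (j in seq_len(nS)) {
    D <- which(R[, j] == 1L)
    sub <- drug_sim$S[, D, drop = FALSE]
    if (length(D) > 0L) sub[cbind(D, seq_along(D))] <- -Inf
    SX[, j] <- row_max(sub, nD)
  }
  # sim_y: per drug, max similarity of each side effect to that drug's
  # related side effects, self-similarity masked out.
  for (i in seq_len(nD)) {
    E <- which(R[i, ] == 1L)
    sub <- se_sim$S[, E, drop = FALSE]
    if (length(E) > 0L) sub[cbind(E, seq_along(E))] <- -Inf
    SY[i, ] <- row_max(sub, nS)
  }
  empty_x <- !is.finite(SX); SX[empty_x] <- 0
  empty_y <- !is.finite(SY); SY[empty_y] <- 0
  score <- SX * SY
  score[empty_x | empty_y] <- 0
  structure(list(score = score, sim_x = SX, sim_y = SY,
                 empty_x = empty_x, empty_y = empty_y,
                 drug_vocab = adj$drug_vocab, se_vocab = adj$se_vocab),
            class = "adr_scores")
}

#' @export
print.adr_scores <- function(x, ...) {
  cat(sprintf("adr_scores: %d x %d pairs (%d masked cells)\n",
              nrow(x$score), ncol(x$score), sum(x$empty_x | x$empty_y)))
  invisible(x)
}

#' @export
dim.adr_scores <- function(x) dim(x$score)

#' Number of scored drug-side-effect pairs
#'
#' @param x An `adr_adjacency` or `adr_scores`, or a drug count (then `y`
#'   must be the side-effect count).
#' @param y Optional side-effect count.
#' @return |drugs| x |side effects| as a double.
#' @export
n_scored_pairs <- function(x, y = NULL) {
  if (inherits(x, "adr_adjacency") || inherits(x, "adr_scores")) {
    d <- dim(x)
    return(as.numeric(d[1L]) * as.numeric(d[2L]))
  }
  as.numeric(x) * as.numeric(y)
}

#' Top-ranked novel (unknown) pairs
#'
#' Ranks the pairs absent from the adjacency by relation score, descending;
#' ties are broken lexicographically by (drug term, side-effect term) so the
#' ranking is deterministic. An optional exclusion list removes user-flagged
#' drugs (e.g. classes used despite known side effects) before ranking.
#'
#' @param scores An `adr_scores`.
#' @param adj The `adr_adjacency` the scores were computed from.
#' @param k Number of pairs to return (clamped to the number of unknown
#'   pairs).
#' @param exclude_drugs Optional character vector of drug terms to drop.
#' @return data.frame with columns `drug`, `se`, `sim_x`, `sim_y`, `score`.
#' @export
top_novel_pairs <- function(scores, adj, k = 1000L, exclude_drugs = NULL) {
  stopifnot(k >= 1L)
  unknown <- which(adj$R == 0L)
  ij <- arrayInd(unknown, dim(adj$R))
  out <- data.frame(drug = rownames(adj$R)[ij[, 1L]],
                    se = colnames(adj$R)[ij[, 2L]],
                    sim_x = scores$sim_x[unknown],
                    sim_y = scores$sim_y[unknown],
                    score = scores$score[unknown],
                    stringsAsFactors = FALSE)
  if (!is.null(exclude_drugs)) {
    out <- out[!out$drug %in% normalize_terms(exclude_drugs), , drop = FALSE]
  }
  ord <- order(-out$score, out$drug, out$se, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Export scores as a long-format TSV
#'
#' One row per drug-side-effect cell: `drug`, `se`, `sim_x`, `sim_y`,
#' `score`, `known` (adjacency value), `masked` (empty related set after
#' exclusion). Rows are in column-major cell order, which is deterministic
#' given the sorted vocabularies.
#'
#' @param scores An `adr_scores`.
#' @param adj The matching `adr_adjacency`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, adj, path) {
  cells <- seq_along(scores$score)
  ij <- arrayInd(cells, dim(scores$score))
  df <- data.frame(drug = rownames(adj$R)[ij[, 1L]],
                   se = colnames(adj$R)[ij[, 2L]],
                   sim_x = scores$sim_x[cells],
                   sim_y = scores$sim_y[cells],
                   score = scores$score[cells],
                   known = adj$R[cells],
                   masked = as.integer(scores$empty_x[cells] | scores$empty_y[cells]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
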