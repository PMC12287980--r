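#' Cosine similarity of two vectors
#'
#' \deqn{\cos(A, B) = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2}\sqrt{\sum_i B_i^2}}}
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero-norm vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

metric_choices <- c("cosine", "euclidean", "manhattan", "jaccard", "dot")

#' Within-axis pairwise similarity matrix
#'
#' Computes the full square term-by-term similarity matrix for one axis,
#' including self-pairs (so an n-term axis yields n^2 cells; exclusion of the
#' query term happens at scoring time, not here). Euclidean and Manhattan
#' distances are converted to similarities by negation, which is
#' parameter-free and order-preserving, so every ranking-based downstream
#' result (ROC/AUC) is identical under any other strictly decreasing
#' transform; the Youden threshold value is then metric-specific and
#' reported as-is. Jaccard on real-valued vectors is the generalized
#' (Ruzicka) form \eqn{\sum_i \min(a_i,b_i) / \sum_i \max(a_i,b_i)}, defined
#' for nonnegative components only; `shift_nonnegative` subtracts the global
#' minimum component first rather than silently binarizing.
#'
#' @param emb An `adr_embeddings` object.
#' @param metric One of `"cosine"`, `"euclidean"`, `"manhattan"`,
#'   `"jaccard"`, `"dot"`.
#' @param shift_nonnegative For `jaccard`: shift all components by the global
#'   minimum so they are nonnegative.
#' @return An `adr_similarity` object: list with `axis`, `metric`, square
#'   matrix `S` (dimnames = terms), and `higher_is_closer = TRUE`.
#' @export
pairwise_similarity <- function(emb, metric = metric_choices,
                                shift_nonnegative = FALSE) {
  stopifnot(inherits(emb, "adr_embeddings"))
  if (length(metric) > 1L) metric <- metric[[1L]]
  if (!metric %in% metric_choices) {
    stop("unknown metric '", metric, "'; choices: ",
         paste(metric_choices, collapse = ", "))
  }
  V <- emb$vectors
  S <- switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(V^2))
      if (any(nrm == 0)) stop("cosine similarity undefined for zero-norm vectors")
      Vn <- V / nrm
      M <- Vn %*% t(Vn)
      M[M > 1] <- 1; M[M < -1] <- -1
      diag(M) <- 1
      M
    },
    dot = V %*% t(V),
    euclidean = -as.matrix(stats::dist(V, method = "euclidean")),
    manhattan = -as.matrix(stats::dist(V, method = "manhattan")),
    jaccard = {
      if (shift_nonnegative) V <- V - min(V)
      if (any(V < 0)) {
        stop("generalized Jaccard requires nonnegative components; ",
             "use shift_nonnegative = TRUE or another metric")
      }
      ruzicka_matrix(V)
    })
  dimnames(S) <- list(rownames(V), rownames(V))
  structure(list(axis = emb$axis, metric = metric, S = S,
                 higher_is_closer = TRUE),
            class = "adr_similarity")
}

# Sum-min / sum-max over all row pairs; identical all-zero rows count as 1.
ruzicka_matrix <- function(V) {
  n <- nrow(V)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    vi <- V[i, ]
    for (j in i:n) {
      vj <- V[j, ]
      den <- sum(pmax(vi, vj))
      S[i, j] <- S[j, i] <- if (den == 0) 1 else sum(pmin(vi, vj)) / den
    }
  }
  S
}

#' @export
print.adr_similarity <- function(x, ...) {
  cat(sprintf("adr_similarity [%s, %s]: %d x %d cells\n",
              x$axis, x$metric, nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Number of within-axis similarity cells
#'
#' Self-pairs included: an axis of n terms has n^2 pairwise similarity cells.
#'
#' @param x An `adr_vocabulary`, `adr_embeddings`, `adr_similarity`, or a
#'   term count.
#' @return The cell count n^2 (as a double, to stay exact past 2^31).
#' @export
n_similarity_cells <- function(x) {
  n <- if (inherits(x, "adr_vocabulary")) length(x)
       else if (inherits(x, "adr_embeddings")) nrow(x$vectors)
       else if (inherits(x, "adr_similarity")) nrow(x$S)
       else as.numeric(x)
  as.numeric(n)^2
}

#' Export a similarity matrix as dense TSV with vocabulary sidecar
#'
#' @param sim An `adr_similarity`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_similarity <- function(sim, dir, prefix = paste0("similarity_", sim$axis)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".tsv", ".terms.txt")))
  utils::write.table(sim$S, paths[1L], sep = "\t", quote = FALSE,
                     col.names = NA)
  writeLines(rownames(sim$S), paths[2L])
  invisible(paths)
}
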