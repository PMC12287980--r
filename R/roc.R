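#' Flatten scores and known-relationship labels into aligned vectors
#'
#' Labels every scored cell 1 if the pair is a known relationship in the
#' adjacency, 0 otherwise. Evaluation is in-sample by design: the known
#' adjacency both drives the related sets and supplies the labels, with the
#' leave-one-out exclusion removing the self-evidence a known pair would
#' otherwise contribute to its own score (see [holdout_roc()] for the
#' held-out alternative). Masked cells (empty related set after exclusion)
#' are included as score-0 cells by default; `drop_masked` removes them.
#'
#' @param scores An `adr_scores`.
#' @param adj The matching `adr_adjacency`.
#' @param drop_masked Drop cells flagged in either empty mask.
#' @return List with `scores`, `labels` (0/1 integer), `n_pos`, `n_neg`.
#' @export
label_pairs <- function(scores, adj, drop_masked = FALSE) {
  if (!identical(dim(scores), dim(adj))) {
    stop("scores and adjacency have different shapes")
  }
  s <- as.vector(scores$score)
  y <- as.integer(as.vector(adj$R))
  if (drop_masked) {
    keep <- !(as.vector(scores$empty_x) | as.vector(scores$empty_y))
    s <- s[keep]; y <- y[keep]
  }
  list(scores = s, labels = y, n_pos = sum(y == 1L), n_neg = sum(y == 0L))
}

#' ROC curve, AUC and Youden-optimal threshold
#'
#' Builds the single ROC curve over all unique score values (a pair is
#' called related when its score strictly exceeds the threshold), computes
#' the AUC both as the trapezoidal area and as the tie-corrected
#' Mann-Whitney rank statistic (the two agree to numerical precision; the
#' rank form is stored as `auc` since it is exact under heavy ties), and
#' selects the threshold maximizing Youden's J = sensitivity + specificity
#' - 1 (equivalently TPR - FPR), taking the smallest qualifying threshold
#' on ties.
#'
#' @param score Numeric score vector.
#' @param label 0/1 label vector aligned with `score` (both classes must be
#'   present).
#' @return An `adr_roc` object: list with `auc`, `auc_trapezoid`,
#'   `thresholds` (descending, ending in `-Inf`), `tpr`, `fpr`,
#'   `optimal_threshold`, `sensitivity_at_opt`, `specificity_at_opt`,
#'   `youden_at_opt`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(score, label) {
  if (length(score) != length(label)) stop("score and label length mismatch")
  label <- as.integer(label)
  n_pos <- sum(label == 1L); n_neg <- sum(label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve")
  }
  # Tie-corrected Mann-Whitney AUC via midranks.
  r <- rank(score)
  auc_rank <- (sum(r[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  u <- sort(unique(score), decreasing = TRUE)
  pos_at <- vapply(split(label, match(score, u)), function(l) sum(l == 1L), 0L)
  cnt_pos <- numeric(length(u)); cnt_all <- numeric(length(u))
  tab <- table(factor(match(score, u), levels = seq_along(u)))
  cnt_all <- as.numeric(tab)
  cnt_pos[as.integer(names(pos_at))] <- as.numeric(pos_at)
  cnt_neg <- cnt_all - cnt_pos
  # Strictly-greater convention: at threshold u[k], predicted positives are
  # the scores above u[k], i.e. the first k-1 unique values.
  tp <- c(0, cumsum(cnt_pos))
  fp <- c(0, cumsum(cnt_neg))
  thresholds <- c(u, -Inf)
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)

  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[length(best)]  # thresholds descend: last index = smallest threshold
  structure(list(auc = auc_rank, auc_trapezoid = auc_trap,
                 thresholds = thresholds, tpr = tpr, fpr = fpr,
                 optimal_threshold = thresholds[best],
                 sensitivity_at_opt = tpr[best],
                 specificity_at_opt = 1 - fpr[best],
                 youden_at_opt = j[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "adr_roc")
}

#' @export
print.adr_roc <- function(x, ...) {
  cat(sprintf(paste0("adr_roc: AUC %.4f, optimal threshold %.4g ",
                     "(sensitivity %.3f, specificity %.3f), %d pos / %d neg\n"),
              x$auc, x$optimal_threshold, x$sensitivity_at_opt,
              x$specificity_at_opt, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.adr_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Evaluate scores against the known adjacency
#'
#' Convenience wrapper: [label_pairs()] then [roc_auc()].
#'
#' @inheritParams label_pairs
#' @return An `adr_roc`.
#' @export
evaluate_scores <- function(scores, adj, drop_masked = FALSE) {
  lp <- label_pairs(scores, adj, drop_masked = drop_masked)
  roc_auc(lp$scores, lp$labels)
}

#' Single-similarity ablation
#'
#' Ranks all pairs by one scoring field — `sim_x_only` (drug similarity
#' information only), `sim_y_only` (side-effect similarity only), or
#' `product` (the full relation score) — and evaluates the ranking against
#' the known adjacency. `product` reproduces the main pipeline.
#'
#' @param adj An `adr_adjacency`.
#' @param drug_sim,se_sim `adr_similarity` matrices.
#' @param mode `"sim_x_only"`, `"sim_y_only"`, or `"product"`.
#' @param scores Optional precomputed `adr_scores` (avoids rescoring when
#'   running several modes).
#' @return An `adr_roc`.
#' @export
ablation_single_similarity <- function(adj, drug_sim, se_sim,
                                       mode = c("product", "sim_x_only", "sim_y_only"),
                                       scores = NULL) {
  mode <- match.arg(mode)
  if (is.null(scores)) scores <- score_all_pairs(adj, drug_sim, se_sim)
  field <- switch(mode,
                  product = scores$score,
                  sim_x_only = scores$sim_x,
                  sim_y_only = scores$sim_y)
  roc_auc(as.vector(field), as.integer(as.vector(adj$R)))
}

#' Held-out evaluation of the scoring pipeline
#'
#' The methodologically stricter alternative to in-sample evaluation: a
#' random fraction of known pairs is masked out of the adjacency, scores are
#' computed from the remainder, and the ROC is evaluated on the masked
#' positives against all unknown cells.
#'
#' @param adj An `adr_adjacency`.
#' @param drug_sim,se_sim `adr_similarity` matrices.
#' @param holdout_fraction Fraction of known pairs to mask (0, 1).
#' @param seed Integer seed controlling the mask.
#' @return List with `roc` (an `adr_roc` over masked positives vs unknown
#'   cells) and `n_held_out`.
#' @export
holdout_roc <- function(adj, drug_sim, se_sim, holdout_fraction = 0.1, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  known <- which(adj$R == 1L)
  n_hold <- max(1L, floor(length(known) * holdout_fraction))
  set.seed(seed)
  held <- sample(known, n_hold)
  adj2 <- adj
  adj2$R[held] <- 0L
  sc <- score_all_pairs(adj2, drug_sim, se_sim)
  eval_cells <- c(held, which(adj$R == 0L))
  lab <- c(rep(1L, length(held)), rep(0L, sum(adj$R == 0L)))
  list(roc = roc_auc(sc$score[eval_cells], lab), n_held_out = n_hold)
}

#' Write a ROC report as JSON
#'
#' @param roc An `adr_roc`.
#' @param path Output JSON path.
#' @param threshold_policy Policy string echoed into the report (e.g.
#'   `"optimal_from_roc"` or `"fixed:0.289"`).
#' @return Invisibly, `path`.
#' @export
write_roc_report <- function(roc, path, threshold_policy = "optimal_from_roc") {
  rep <- list(auc = roc$auc,
              optimal_threshold = roc$optimal_threshold,
              sensitivity = roc$sensitivity_at_opt,
              specificity = roc$specificity_at_opt,
              n_pos = roc$n_pos, n_neg = roc$n_neg,
              threshold_policy = threshold_policy)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC curve points as TSV
#'
#' @param roc An `adr_roc`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                                fpr = roc$fpr),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
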