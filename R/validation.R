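#' Threshold scores into binary relation predictions
#'
#' A pair is predicted related when its relation score strictly exceeds the
#' diagnostic threshold (a score exactly equal to the threshold is predicted
#' not related).
#'
#' @param scores An `adr_scores` or a numeric matrix of scores.
#' @param threshold Numeric cut-off.
#' @return Integer 0/1 matrix of the same shape.
#' @export
predict_labels <- function(scores, threshold) {
  S <- if (inherits(scores, "adr_scores")) scores$score else as.matrix(scores)
  P <- matrix(as.integer(S > threshold), nrow = nrow(S), ncol = ncol(S),
              dimnames = dimnames(S))
  P
}

#' Odds ratio of a 2x2 contingency table
#'
#' The cross-product ratio (a*d)/(b*c). If any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell first, so the ratio is
#' always finite and positive. The table convention is rows = externally
#' known vs unknown pair, columns = predicted related vs not:
#' `a` known & predicted, `b` known & not predicted, `c` unknown &
#' predicted, `d` unknown & not predicted.
#'
#' @param a Count, or a 2x2 matrix `rbind(c(a, b), c(c, d))` (then `b`,
#'   `c`, `d` are ignored).
#' @param b,c,d Counts.
#' @return The (possibly corrected) odds ratio.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("contingency counts must be nonnegative")
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
}

#' Balanced-resampling Fisher exact validation against an external extract
#'
#' Validates thresholded predictions against an independent relation source
#' (e.g. a spontaneous-report extract): per repeat, all externally known
#' pairs are kept and an equal number of externally unknown pairs is sampled
#' uniformly without replacement, a 2x2 table of external status vs
#' prediction is built, and a two-sided Fisher exact test p-value plus the
#' cross-product odds ratio ([odds_ratio()], Haldane-Anscombe corrected on
#' zeros) are computed. Results are aggregated by the arithmetic mean over
#' repeats; the median is reported alongside as a robustness check. The
#' whole procedure is reproducible from `seed` (one seeded generator,
#' repeats drawn in order).
#'
#' @param predictions Binary drugs-by-side-effects matrix with term dimnames
#'   (see [predict_labels()]).
#' @param external An `adr_relations` with the external pairs; pairs outside
#'   the prediction vocabularies are dropped (with a message).
#' @param n_repeats Number of resampling repeats.
#' @param seed Integer RNG seed.
#' @return An `adr_validation` object: list with `n_repeats`, `mean_p`,
#'   `mean_or`, `median_p`, `median_or`, `per_repeat` (data.frame of `p`,
#'   `or`), `n_known`, `seed`.
#' @export
balanced_fisher_validation <- function(predictions, external,
                                       n_repeats = 2000L, seed = 1L) {
  stopifnot(inherits(external, "adr_relations"), n_repeats >= 1L)
  drugs <- rownames(predictions); ses <- colnames(predictions)
  if (is.null(drugs) || is.null(ses)) stop("predictions must carry term dimnames")
  p <- external$pairs
  inside <- p$drug %in% drugs & p$se %in% ses
  if (any(!inside)) {
    message(sum(!inside), " external pair(s) outside the vocabularies dropped")
    p <- p[inside, , drop = FALSE]
  }
  if (nrow(p) == 0L) stop("external relation set is empty after restriction")
  known <- unique((match(p$se, ses) - 1L) * nrow(predictions) + match(p$drug, drugs))
  n_cells <- length(predictions)
  unknown <- setdiff(seq_len(n_cells), known)
  n_known <- length(known)
  if (length(unknown) < n_known) {
    stop("fewer externally unknown pairs (", length(unknown),
         ") than known pairs (", n_known, "); cannot balance the sample")
  }
  pred_known <- predictions[known]
  a <- sum(pred_known == 1L)           # fixed across repeats
  b <- n_known - a
  set.seed(seed)
  per <- vapply(seq_len(n_repeats), function(rep) {
    samp <- sample(unknown, n_known)
    cc <- sum(predictions[samp] == 1L)
    dd <- n_known - cc
    tab <- matrix(c(a, cc, b, dd), nrow = 2L)
    c(p = stats::fisher.test(tab)$p.value,
      or = odds_ratio(a, b, cc, dd))
  }, c(p = 0, or = 0))
  per_repeat <- data.frame(p = per["p", ], or = per["or", ])
  structure(list(n_repeats = n_repeats,
                 mean_p = mean(per_repeat$p), mean_or = mean(per_repeat$or),
                 median_p = stats::median(per_repeat$p),
                 median_or = stats::median(per_repeat$or),
                 per_repeat = per_repeat, n_known = n_known, seed = seed),
            class = "adr_validation")
}

#' @export
print.adr_validation <- function(x, ...) {
  cat(sprintf(paste0("adr_validation: %d repeats of %d known vs %d sampled ",
                     "unknown pairs\n  mean OR %.3f (median %.3f), mean p %.3g ",
                     "(median %.3g)\n"),
              x$n_repeats, x$n_known, x$n_known, x$mean_or, x$median_or,
              x$mean_p, x$median_p))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param val An `adr_validation`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(val, path) {
  rep <- list(n_repeats = val$n_repeats, n_known = val$n_known,
              mean_p = val$mean_p, mean_or = val$mean_or,
              median_p = val$median_p, median_or = val$median_or,
              seed = val$seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
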