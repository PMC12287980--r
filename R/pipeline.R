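#' Assemble a pipeline run configuration
#'
#' Two input modes share one code path. File mode reads a relation TSV and
#' word-vector files (plus an optional external extract TSV); synthetic mode
#' generates all three with [generate_benchmark()] and
#' [generate_external_extract()]. Exactly one threshold policy is active:
#' `"optimal_from_roc"` (Youden) or `"fixed:<value>"`.
#'
#' @param out_dir Output directory for run artifacts.
#' @param relations,drug_vectors,se_vectors,external Input paths (file
#'   mode); leave `NULL` for synthetic mode.
#' @param synthetic An `adr_synth_config` (synthetic mode), or `NULL`.
#' @param metric Similarity metric (see [pairwise_similarity()]).
#' @param threshold_policy `"optimal_from_roc"` or `"fixed:<value>"`.
#' @param external_enrichment,external_pairs Synthetic external extract
#'   parameters.
#' @param n_repeats Fisher validation repeats.
#' @param seed Master seed; stage seeds are derived from it.
#' @return An `adr_run_config` list.
#' @export
run_config <- function(out_dir,
                       relations = NULL, drug_vectors = NULL,
                       se_vectors = NULL, external = NULL,
                       synthetic = NULL,
                       metric = "cosine",
                       threshold_policy = "optimal_from_roc",
                       external_enrichment = 8, external_pairs = 400L,
                       n_repeats = 500L, seed = 1L) {
  file_mode <- !is.null(relations)
  if (file_mode && is.null(drug_vectors)) stop("file mode needs drug_vectors")
  if (file_mode && is.null(se_vectors)) stop("file mode needs se_vectors")
  if (!file_mode && is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  if (!grepl("^(optimal_from_roc|fixed:-?[0-9.eE+-]+)$", threshold_policy)) {
    stop("threshold_policy must be 'optimal_from_roc' or 'fixed:<value>'")
  }
  structure(list(out_dir = out_dir, relations = relations,
                 drug_vectors = drug_vectors, se_vectors = se_vectors,
                 external = external, synthetic = synthetic, metric = metric,
                 threshold_policy = threshold_policy,
                 external_enrichment = external_enrichment,
                 external_pairs = as.integer(external_pairs),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "adr_run_config")
}

log_line <- function(lines, ...) c(lines, sprintf(...))

#' Run the full scoring-evaluation-validation pipeline
#'
#' Executes every stage on one configuration and writes four artifacts into
#' `config$out_dir`: `scores.tsv` (long-format scores), `roc.json` (AUC,
#' threshold, sensitivity/specificity), `validation.json` (balanced Fisher
#' summary; only when an external extract is available), and `run.log`
#' (package version, config values and seeds, per-stage records). Files are
#' written atomically (temp file then rename). Inputs are checked up front,
#' so a missing path fails before any artifact is produced; a rerun with
#' identical config and inputs is byte-identical.
#'
#' @param config An `adr_run_config` (see [run_config()]).
#' @return Invisibly, a list with the in-memory stage results (`adjacency`,
#'   `scores`, `roc`, `threshold`, `validation`) and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "adr_run_config"))
  file_mode <- !is.null(config$relations)
  if (file_mode) {
    for (p in c(config$relations, config$drug_vectors, config$se_vectors,
                config$external)) {
      if (!file.exists(p)) stop("[input] file not found: ", p)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- character(0)
  lg <- log_line(lg, "adrscore %s | R %s.%s",
                 as.character(utils::packageVersion("adrscore")),
                 R.version$major, R.version$minor)
  cfg_flat <- config
  cfg_flat$synthetic <- if (is.null(config$synthetic)) NULL else
    unclass(config$synthetic)
  lg <- log_line(lg, "config: %s",
                 jsonlite::toJSON(cfg_flat[!vapply(cfg_flat, is.null, TRUE)],
                                  auto_unbox = TRUE))

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
    lg <<- log_line(lg, "stage %s: ok", name)
    res
  }

  external_rel <- NULL
  if (file_mode) {
    rel <- stage("relations", read_relation_table(config$relations))
    adj <- stage("adjacency", build_adjacency(rel))
    d_emb <- stage("drug_vectors",
                   load_word_vectors(config$drug_vectors, adj$drug_vocab))
    s_emb <- stage("se_vectors",
                   load_word_vectors(config$se_vectors, adj$se_vocab))
    if (!is.null(config$external)) {
      external_rel <- stage("external", read_relation_table(config$external))
    }
  } else {
    bench <- stage("simulate", generate_benchmark(config$synthetic))
    adj <- stage("adjacency", build_adjacency(bench$relations))
    d_emb <- bench$drug_embeddings
    s_emb <- bench$se_embeddings
  }
  drug_sim <- stage("similarity_drug", pairwise_similarity(d_emb, config$metric))
  se_sim <- stage("similarity_se", pairwise_similarity(s_emb, config$metric))
  scores <- stage("score", score_all_pairs(adj, drug_sim, se_sim))
  roc <- stage("evaluate", evaluate_scores(scores, adj))
  threshold <- if (config$threshold_policy == "optimal_from_roc") {
    roc$optimal_threshold
  } else {
    as.numeric(sub("^fixed:", "", config$threshold_policy))
  }
  lg <- log_line(lg, "threshold policy %s -> threshold %.10g",
                 config$threshold_policy, threshold)
  if (!file_mode) {
    external_rel <- stage("external",
                          generate_external_extract(
                            scores, enrichment = config$external_enrichment,
                            n_pairs = config$external_pairs,
                            seed = config$seed + 1L))
  }
  validation <- NULL
  if (!is.null(external_rel)) {
    preds <- predict_labels(scores, threshold)
    validation <- stage("validate",
                        balanced_fisher_validation(preds, external_rel,
                                                   n_repeats = config$n_repeats,
                                                   seed = config$seed + 2L))
  }

  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
    path
  }
  paths <- list(
    scores = atomically(file.path(config$out_dir, "scores.tsv"),
                        function(p) write_scores(scores, adj, p)),
    roc = atomically(file.path(config$out_dir, "roc.json"),
                     function(p) write_roc_report(roc, p,
                                                  config$threshold_policy)))
  if (!is.null(validation)) {
    paths$validation <- atomically(file.path(config$out_dir, "validation.json"),
                                   function(p) write_validation_report(validation, p))
  }
  lg <- log_line(lg, "artifacts: %s",
                 paste(basename(unlist(paths)), collapse = ", "))
  paths$log <- file.path(config$out_dir, "run.log")
  writeLines(lg, paths$log)
  invisible(list(adjacency = adj, scores = scores, roc = roc,
                 threshold = threshold, validation = validation,
                 paths = paths))
}
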