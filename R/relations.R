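#' Normalize relation terms
#'
#' Lowercases and strips surrounding whitespace. This is the desk-scale proxy
#' for the identifier standardization (PubChem CIDs, MedDRA preferred terms)
#' that curated resources apply upstream; an optional mapping file can merge
#' synonyms on top of it (see [read_relation_table()]).
#'
#' @param x Character vector of terms.
#' @return Character vector of normalized terms.
#' @export
normalize_terms <- function(x) {
  trimws(tolower(as.character(x)))
}

#' Construct a term vocabulary for one axis
#'
#' A vocabulary is the ordered, unique term list for either the drug axis or
#' the side-effect axis. Order is the lexicographic sort of the (optionally
#' normalized) terms, so every matrix built on top of it is reproducible
#' across runs and platforms.
#'
#' @param terms Character vector of terms (duplicates allowed; removed).
#' @param axis `"drug"` or `"side_effect"`.
#' @param normalize Lowercase and trim terms before deduplication.
#' @return An object of class `adr_vocabulary`: list with `axis` and sorted
#'   unique `terms`.
#' @export
vocabulary <- function(terms, axis = c("drug", "side_effect"), normalize = TRUE) {
  axis <- match.arg(axis)
  if (normalize) terms <- normalize_terms(terms)
  terms <- sort(unique(terms[nzchar(terms)]), method = "radix")
  if (length(terms) < 1L) stop("vocabulary must contain at least one term")
  structure(list(axis = axis, terms = terms), class = "adr_vocabulary")
}

#' @export
length.adr_vocabulary <- function(x) length(x$terms)

#' @export
print.adr_vocabulary <- function(x, ...) {
  cat(sprintf("adr_vocabulary [%s]: %d terms\n", x$axis, length(x$terms)))
  invisible(x)
}

#' Look up vocabulary positions of terms
#'
#' @param vocab An `adr_vocabulary`.
#' @param terms Character vector of terms.
#' @return Integer positions (1-based); error if any term is absent.
#' @export
vocab_index <- function(vocab, terms) {
  i <- match(terms, vocab$terms)
  if (anyNA(i)) {
    stop("terms not in ", vocab$axis, " vocabulary: ",
         paste(utils::head(terms[is.na(i)], 5L), collapse = ", "))
  }
  i
}

#' Build an in-memory relation table
#'
#' @param drug,se Character vectors of equal length: one (drug, side effect)
#'   pair per element. Duplicate pairs are removed.
#' @param source_label Free-text provenance label.
#' @param normalize Lowercase and trim terms.
#' @return An `adr_relations` object: list with `pairs` (data.frame with
#'   columns `drug`, `se`), `source_label`, and `n_duplicates` (count removed).
#' @export
relation_table <- function(drug, se, source_label = "memory", normalize = TRUE) {
  drug <- as.character(drug); se <- as.character(se)
  if (length(drug) != length(se)) stop("drug and se must have equal length")
  if (normalize) { drug <- normalize_terms(drug); se <- normalize_terms(se) }
  bad <- !nzchar(drug) | !nzchar(se)
  if (any(bad)) stop("empty term in relation pair(s): row ", which(bad)[1L])
  key <- paste(drug, se, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(drug = drug[!dup], se = se[!dup], stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("relation table is empty")
  structure(list(pairs = out, source_label = source_label,
                 n_duplicates = sum(dup)),
            class = "adr_relations")
}

#' @export
print.adr_relations <- function(x, ...) {
  cat(sprintf("adr_relations '%s': %d unique pairs (%d duplicates removed)\n",
              x$source_label, nrow(x$pairs), x$n_duplicates))
  invisible(x)
}

#' Read a drug-side-effect relation table from TSV
#'
#' Ingests a SIDER-style tab-separated relation file: one row per known
#' (drug, side effect) pair, columns selectable by index. Duplicate pairs are
#' removed and counted, so users can reconcile against published pair totals
#' that depend on upstream term collapsing.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param drug_col,se_col 1-based column indices of the drug and side-effect
#'   terms.
#' @param normalize Lowercase and trim terms (default on).
#' @param header Logical; skip the first row.
#' @param mapping Optional synonym map: a named character vector or a
#'   two-column TSV path (`term<TAB>canonical`), applied after normalization
#'   to both axes. Emulates identifier-based synonym merging.
#' @param source_label Provenance label; defaults to the file name.
#' @return An `adr_relations` object (see [relation_table()]).
#' @export
read_relation_table <- function(path, drug_col = 1L, se_col = 2L,
                                normalize = TRUE, header = FALSE,
                                mapping = NULL, source_label = basename(path)) {
  if (!file.exists(path)) stop("relation file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines_no <- seq_along(lines) + as.integer(header)
  keep <- nzchar(lines)
  lines <- lines[keep]; lines_no <- lines_no[keep]
  if (length(lines) == 0L) stop("relation file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(drug_col, se_col)
  nf <- lengths(fields)
  if (any(nf < need)) {
    stop(sprintf("malformed row at line %d: %d field(s), need at least %d",
                 lines_no[which(nf < need)[1L]], nf[which(nf < need)[1L]], need))
  }
  drug <- vapply(fields, `[[`, character(1L), drug_col)
  se <- vapply(fields, `[[`, character(1L), se_col)
  if (normalize) { drug <- normalize_terms(drug); se <- normalize_terms(se) }
  if (!is.null(mapping)) {
    map <- read_term_mapping(mapping)
    drug <- remap_terms(drug, map)
    se <- remap_terms(se, map)
  }
  rel <- relation_table(drug, se, source_label = source_label, normalize = FALSE)
  if (rel$n_duplicates > 0L) {
    message(rel$n_duplicates, " duplicate pair(s) removed from ", source_label)
  }
  rel
}

read_term_mapping <- function(mapping) {
  if (is.character(mapping) && is.null(names(mapping)) && length(mapping) == 1L &&
      file.exists(mapping)) {
    m <- utils::read.delim(mapping, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    stats::setNames(normalize_terms(m[[2L]]), normalize_terms(m[[1L]]))
  } else if (is.character(mapping) && !is.null(names(mapping))) {
    stats::setNames(normalize_terms(mapping), normalize_terms(names(mapping)))
  } else {
    stop("mapping must be a named character vector or a two-column TSV path")
  }
}

remap_terms <- function(x, map) {
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Build the binary drug-by-side-effect adjacency matrix
#'
#' Vocabularies are induced from the observed pairs (sorted unique terms per
#' axis), and the adjacency entry `R[i, j]` is 1 exactly when drug i and side
#' effect j co-occur in the relation table. Construction is lossless:
#' enumerating the 1-cells recovers the input pair set, and the matrix sum
#' equals the number of unique pairs.
#'
#' @param rel An `adr_relations` object.
#' @return An `adr_adjacency` object: list with integer 0/1 matrix `R`
#'   (dimnames = terms), `drug_vocab` and `se_vocab`.
#' @export
build_adjacency <- function(rel) {
  stopifnot(inherits(rel, "adr_relations"))
  dv <- vocabulary(rel$pairs$drug, "drug", normalize = FALSE)
  sv <- vocabulary(rel$pairs$se, "side_effect", normalize = FALSE)
  R <- matrix(0L, nrow = length(dv), ncol = length(sv),
              dimnames = list(dv$terms, sv$terms))
  R[cbind(vocab_index(dv, rel$pairs$drug), vocab_index(sv, rel$pairs$se))] <- 1L
  structure(list(R = R, drug_vocab = dv, se_vocab = sv),
            class = "adr_adjacency")
}

#' @export
print.adr_adjacency <- function(x, ...) {
  cat(sprintf("adr_adjacency: %d drugs x %d side effects, %d known pairs\n",
              nrow(x$R), ncol(x$R), sum(x$R)))
  invisible(x)
}

#' @export
dim.adr_adjacency <- function(x) dim(x$R)

resolve_index <- function(x, n, vocab, what) {
  if (is.character(x)) return(vocab_index(vocab, x))
  x <- as.integer(x)
  if (any(x < 1L | x > n)) stop(what, " index out of range [1, ", n, "]")
  x
}

#' Drugs known to be associated with a side effect
#'
#' The related-drug set used by the scoring step: all drugs whose adjacency
#' entry with the given side effect is 1.
#'
#' @param adj An `adr_adjacency`.
#' @param se Side-effect term or 1-based column index.
#' @return Named integer vector of drug row indices (possibly empty for a
#'   hand-built matrix; always nonempty when `adj` came from a relation
#'   table).
#' @export
related_drugs <- function(adj, se) {
  j <- resolve_index(se, ncol(adj$R), adj$se_vocab, "side effect")
  stopifnot(length(j) == 1L)
  i <- which(adj$R[, j] == 1L)
  stats::setNames(i, rownames(adj$R)[i])
}

#' Side effects known to be associated with a drug
#'
#' Row mirror of [related_drugs()].
#'
#' @param adj An `adr_adjacency`.
#' @param drug Drug term or 1-based row index.
#' @return Named integer vector of side-effect column indices.
#' @export
related_side_effects <- function(adj, drug) {
  i <- resolve_index(drug, nrow(adj$R), adj$drug_vocab, "drug")
  stopifnot(length(i) == 1L)
  j <- which(adj$R[i, ] == 1L)
  stats::setNames(j, colnames(adj$R)[j])
}

#' Export adjacency as Matrix Market plus vocabulary sidecars
#'
#' Writes `<prefix>.mtx` (sparse coordinate format) and two plain-text term
#' lists `<prefix>.drugs.txt` / `<prefix>.side_effects.txt`, one term per
#' line in matrix row/column order.
#'
#' @param adj An `adr_adjacency`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_adjacency <- function(adj, dir, prefix = "adjacency") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", ".drugs.txt", ".side_effects.txt")))
  ones <- which(adj$R == 1L, arr.ind = TRUE)
  Matrix::writeMM(Matrix::sparseMatrix(i = ones[, 1L], j = ones[, 2L],
                                       x = 1, dims = dim(adj$R)),
                  paths[1L])
  writeLines(rownames(adj$R), paths[2L])
  writeLines(colnames(adj$R), paths[3L])
  invisible(paths)
}
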