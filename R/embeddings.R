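#' Construct an embedding set for one axis
#'
#' @param vectors Numeric matrix, one row per term (rownames are terms), all
#'   rows the same dimension.
#' @param axis `"drug"` or `"side_effect"`.
#' @param backend_label Free-text provenance of the vectors.
#' @param allow_zero Permit all-zero vectors (default off: a zero vector has
#'   no direction and silently corrupts cosine ranks).
#' @return An `adr_embeddings` object: list with `axis`, `dim`, `vectors`,
#'   `backend_label`.
#' @export
embedding_set <- function(vectors, axis = c("drug", "side_effect"),
                          backend_label = "user", allow_zero = FALSE) {
  axis <- match.arg(axis)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (is.null(rownames(vectors))) stop("vectors must have term rownames")
  if (anyDuplicated(rownames(vectors))) stop("duplicate terms in embedding set")
  if (!allow_zero) {
    z <- rowSums(vectors^2) == 0
    if (any(z)) {
      stop("all-zero vector(s) for term(s): ",
           paste(utils::head(rownames(vectors)[z], 5L), collapse = ", "),
           " (set allow_zero = TRUE to permit)")
    }
  }
  structure(list(axis = axis, dim = ncol(vectors), vectors = vectors,
                 backend_label = backend_label),
            class = "adr_embeddings")
}

#' @export
print.adr_embeddings <- function(x, ...) {
  cat(sprintf("adr_embeddings [%s]: %d terms x dim %d (backend: %s)\n",
              x$axis, nrow(x$vectors), x$dim, x$backend_label))
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' Parses the plain-text word-vector dialect: an optional `"<count> <dim>"`
#' header line, then one line per term of `term v1 v2 ... vD` separated by
#' whitespace (multi-word terms must use underscores, as word2vec tools emit
#' them). When a vocabulary is supplied, the result is restricted to it and
#' coverage is reported.
#'
#' @param path Path to the vector file.
#' @param vocab Optional `adr_vocabulary` to restrict/check against.
#' @param axis Axis label when `vocab` is absent.
#' @param on_missing Policy for vocabulary terms absent from the file:
#'   `"error"` (default; silent fallbacks corrupt similarity ranks),
#'   `"skip"` (drop them with a warning), or `"zero"` (all-zero vector,
#'   flagged via `allow_zero`).
#' @return An `adr_embeddings` object.
#' @export
load_word_vectors <- function(path, vocab = NULL,
                              axis = c("drug", "side_effect"),
                              on_missing = c("error", "skip", "zero")) {
  on_missing <- match.arg(on_missing)
  axis <- if (is.null(vocab)) match.arg(axis) else vocab$axis
  if (!file.exists(path)) stop("vector file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("vector file is empty: ", path)
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  has_header <- length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))
  offset <- as.integer(has_header)
  body <- lines[(1L + offset):length(lines)]
  if (length(body) == 0L) stop("vector file has a header but no vectors: ", path)
  toks <- strsplit(trimws(body), "[ \t]+")
  dims <- lengths(toks) - 1L
  dim <- if (has_header) as.integer(first[[2L]]) else dims[[1L]]
  bad <- which(dims != dim)
  if (length(bad) > 0L) {
    stop(sprintf("dimension mismatch at line %d: %d value(s), expected %d",
                 bad[1L] + offset, dims[bad[1L]], dim))
  }
  terms <- vapply(toks, `[[`, character(1L), 1L)
  vals <- vapply(toks, function(t) as.numeric(t[-1L]), numeric(dim))
  V <- if (dim == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(V)) stop("non-numeric vector component in ", path)
  rownames(V) <- terms
  if (anyDuplicated(terms)) {
    V <- V[!duplicated(terms), , drop = FALSE]
    warning("duplicate term lines in ", path, "; first occurrence kept")
  }
  if (is.null(vocab)) {
    return(embedding_set(V, axis, backend_label = basename(path)))
  }
  covered <- vocab$terms %in% rownames(V)
  message(sprintf("vector coverage: %d/%d %s terms covered, %d missing",
                  sum(covered), length(vocab), axis, sum(!covered)))
  if (!all(covered)) {
    miss <- vocab$terms[!covered]
    if (on_missing == "error") {
      stop("term(s) without vectors: ",
           paste(utils::head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) sprintf(" ... (%d total)", length(miss)) else "")
    } else if (on_missing == "skip") {
      warning(length(miss), " vocabulary term(s) skipped (no vector)")
    }
  }
  if (on_missing == "zero" && !all(covered)) {
    Z <- matrix(0, nrow = sum(!covered), ncol = ncol(V),
                dimnames = list(vocab$terms[!covered], NULL))
    V <- rbind(V[intersect(vocab$terms, rownames(V)), , drop = FALSE], Z)
    V <- V[vocab$terms, , drop = FALSE]
    return(embedding_set(V, axis, backend_label = basename(path), allow_zero = TRUE))
  }
  keep <- vocab$terms[covered]
  embedding_set(V[keep, , drop = FALSE], axis, backend_label = basename(path))
}

#' Write word vectors in word2vec text format
#'
#' @param emb An `adr_embeddings` object.
#' @param path Output path.
#' @param header Write the `"<count> <dim>"` header line.
#' @param digits Significant digits per component (8 keeps round-trip error
#'   below 1e-6 relative).
#' @return Invisibly, `path`.
#' @export
write_word_vectors <- function(emb, path, header = TRUE, digits = 8L) {
  stopifnot(inherits(emb, "adr_embeddings"))
  V <- emb$vectors
  body <- paste(rownames(V),
                apply(V, 1L, function(v) paste(sprintf("%.*g", digits, v),
                                               collapse = " ")))
  out <- if (header) c(paste(nrow(V), ncol(V)), body) else body
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Encode terms with a pluggable context-free encoder backend
#'
#' Each term is encoded independently as a standalone sequence and pooled to
#' one fixed-dimension vector. `mean_tokens` averages the final-layer token
#' vectors excluding special tokens (the standard context-free term-embedding
#' choice, symmetric in token order); `first_token` takes the first
#' non-special token vector. Encoding is deterministic given the backend.
#'
#' A backend is a list with an `encode(term)` function returning either a
#' numeric token-by-dimension matrix, or a list with elements `tokens` (the
#' matrix, special tokens included) and `special` (logical per row). Passing
#' a model-id string for a backend that is not installed locally raises an
#' error directing you to [load_word_vectors()]: the scoring pipeline never
#' requires network access. [hash_encoder()] provides a deterministic,
#' dependency-free synthetic backend for testing and examples.
#'
#' @param terms Character vector of terms to encode.
#' @param backend Encoder backend (list with `encode`) or a model-id string.
#' @param pooling `"mean_tokens"` or `"first_token"`.
#' @param layer Hidden layer pooled; only `"last_hidden"` is implemented.
#' @param axis Axis label for the result.
#' @return An `adr_embeddings` object with `dim` equal to the encoder's
#'   hidden size.
#' @export
encode_terms <- function(terms, backend,
                         pooling = c("mean_tokens", "first_token"),
                         layer = c("last_hidden"),
                         axis = c("drug", "side_effect")) {
  pooling <- match.arg(pooling)
  layer <- match.arg(layer)
  axis <- match.arg(axis)
  if (length(terms) == 0L) stop("terms must be nonempty")
  if (is.character(backend)) {
    stop("encoder backend '", backend, "' is not available locally; ",
         "export its vectors and use load_word_vectors() instead ",
         "(the pipeline never requires network access)")
  }
  if (!is.list(backend) || !is.function(backend$encode)) {
    stop("backend must be a list with an encode(term) function")
  }
  vecs <- lapply(terms, function(term) {
    enc <- backend$encode(term)
    if (is.matrix(enc)) enc <- list(tokens = enc, special = rep(FALSE, nrow(enc)))
    tok <- enc$tokens[!enc$special, , drop = FALSE]
    if (nrow(tok) == 0L) stop("no non-special tokens for term: ", term)
    switch(pooling,
           mean_tokens = colMeans(tok),
           first_token = tok[1L, ])
  })
  V <- do.call(rbind, vecs)
  rownames(V) <- terms
  label <- if (!is.null(backend$label)) backend$label else "encoder"
  embedding_set(V, axis, backend_label = sprintf("%s/%s/%s", label, layer, pooling))
}

#' Deterministic character-hash encoder backend (synthetic)
#'
#' A dependency-free stand-in encoder for tests and examples: each
#' whitespace-separated token of a term maps, via a polynomial character
#' hash, to a fixed pseudo-random unit-scale vector of sinusoids. The same
#' string always yields the same vectors; distinct strings almost surely
#' differ. The vectors carry no linguistic meaning.
#'
#' @param dim Embedding dimension.
#' @return A backend list usable with [encode_terms()].
#' @export
hash_encoder <- function(dim = 16L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  token_vec <- function(token) {
    h <- 0
    for (cp in utf8ToInt(token)) h <- (h * 131 + cp) %% 1048573
    sin(h * 1e-3 * seq_len(dim) + (h %% 97) * 0.1)
  }
  list(
    label = sprintf("hash-%d", dim),
    encode = function(term) {
      toks <- strsplit(trimws(term), "[ \t]+")[[1L]]
      if (length(toks) == 0L) stop("cannot encode empty term")
      m <- do.call(rbind, lapply(toks, token_vec))
      list(tokens = m, special = rep(FALSE, nrow(m)))
    }
  )
}
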