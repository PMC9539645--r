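# Word embeddings for topic coherence and synonym expansion: a skip-gram
# model with negative sampling, trained on the full retained corpus. The
# trainer (compiled, single-threaded, own RNG) is deterministic given the
# seed, so embeddings, coherence scores, and synonym lists are reproducible.

#' Train a skip-gram word embedding on a tokenized corpus
#'
#' @param corpus A `tokenized_corpus` (all retained posts); alternatively a
#'   plain list of character vectors of terms.
#' @param dim Embedding dimension (default 100).
#' @param window Context window half-width (default 5).
#' @param min_count Terms occurring fewer times are dropped from the
#'   embedding vocabulary (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate (default 0.025, linearly decayed).
#' @param seed Integer seed; identical seed and corpus give identical
#'   vectors.
#' @return `word_embedding`: `vectors` (terms x dim matrix with term
#'   rownames) and `params`.
#' @export
train_embedding <- function(corpus, dim = 100L, window = 5L, min_count = 5L,
                            epochs = 5L, negative = 5L, alpha = 0.025,
                            seed = 1L) {
  docs <- if (is.data.frame(corpus)) corpus$terms else corpus
  if (length(docs) == 0L) stop("empty corpus")
  counts <- table(unlist(docs, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) {
    stop("no term reaches min_count = ", min_count)
  }
  vocab <- sort(names(counts), method = "radix")
  counts <- as.numeric(counts[vocab])

  idx_docs <- lapply(docs, function(tt) {
    ix <- match(tt, vocab)
    as.integer(ix[!is.na(ix)] - 1L)
  })
  idx_docs <- idx_docs[lengths(idx_docs) > 1L]
  if (length(idx_docs) == 0L) stop("no document has >= 2 in-vocabulary terms")

  V <- .sgns_train(idx_docs, length(vocab), counts,
                   as.integer(dim), as.integer(window), as.integer(negative),
                   as.integer(epochs), alpha, as.integer(seed))
  rownames(V) <- vocab
  structure(list(vectors = V,
                 params = list(dim = dim, window = window,
                               min_count = min_count, epochs = epochs,
                               negative = negative, alpha = alpha,
                               seed = seed)),
            class = "word_embedding")
}

#' Construct a word embedding from precomputed vectors
#'
#' Useful for testing and for loading externally trained vectors.
#'
#' @param vectors Numeric matrix, one row per term, with term rownames.
#' @return A `word_embedding`.
#' @export
word_embedding <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(list(vectors = vectors, params = list(dim = ncol(vectors))),
            class = "word_embedding")
}

#' Cosine similarity between two embedded terms
#'
#' @param embedding A `word_embedding`.
#' @param a,b Terms.
#' @return Cosine similarity, or `NA` if either term is out of vocabulary.
#' @export
embedding_similarity <- function(embedding, a, b) {
  V <- embedding$vectors
  if (!a %in% rownames(V) || !b %in% rownames(V)) return(NA_real_)
  va <- V[a, ]; vb <- V[b, ]
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Nearest-neighbor synonyms of a term
#'
#' The `topn` most similar terms by cosine similarity in the embedding
#' space, never including the query itself. Embedding neighbors reflect
#' distributional similarity, so antonym-style neighbors can appear; no
#' filtering is applied.
#'
#' @param term Query term.
#' @param embedding A `word_embedding`.
#' @param topn Number of neighbors (default 5).
#' @return Character vector of terms (empty, with a warning, when the query
#'   is out of vocabulary); similarity scores as names-preserving attribute
#'   `similarity`.
#' @export
synonyms <- function(term, embedding, topn = 5L) {
  V <- embedding$vectors
  if (!term %in% rownames(V)) {
    warning("term not in embedding vocabulary: ", term)
    return(character(0))
  }
  Vn <- V / sqrt(rowSums(V^2))
  sims <- drop(Vn %*% Vn[term, ])
  sims <- sims[names(sims) != term]
  ord <- order(-sims, names(sims), method = "radix")
  topn <- min(topn, length(sims))
  out <- names(sims)[ord][seq_len(topn)]
  structure(out, similarity = unname(sims[ord][seq_len(topn)]))
}

#' Write an embedding in word2vec text format
#'
#' First line `"<n_terms> <dim>"`, then one `term v1 ... vd` line per term.
#'
#' @param embedding A `word_embedding`.
#' @param path Output file.
#' @export
write_embedding <- function(embedding, path) {
  V <- embedding$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  for (i in seq_len(nrow(V))) {
    writeLines(paste(rownames(V)[i],
                     paste(formatC(V[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @export
print.word_embedding <- function(x, ...) {
  cat(sprintf("Word embedding: %d terms x %d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}
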