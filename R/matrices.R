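# Global vocabulary and per-window nonnegative TF-IDF matrices.
#
# All windows share one lexicographically ordered vocabulary so that the
# per-window topic-term matrices can later be stacked column-aligned.

#' Build the global vocabulary
#'
#' Union of all terms over all windows, lexicographically ordered (C locale)
#' so that rebuilding is deterministic. No frequency pruning by default.
#'
#' @param corpus A `tokenized_corpus` (see [preprocess_corpus()]).
#' @param min_df Optional minimum document frequency; terms appearing in
#'   fewer posts are pruned (default 1 = keep everything).
#' @return Character vector of distinct terms, sorted; class `vocabulary`.
#' @export
build_vocabulary <- function(corpus, min_df = 1L) {
  all_terms <- unlist(corpus$terms, use.names = FALSE)
  if (length(all_terms) == 0L) stop("empty corpus: no terms to build a vocabulary from")
  if (min_df > 1L) {
    df <- table(unlist(lapply(corpus$terms, unique), use.names = FALSE))
    keep <- names(df)[df >= min_df]
    all_terms <- all_terms[all_terms %in% keep]
    if (length(all_terms) == 0L) stop("min_df pruned the entire vocabulary")
  }
  v <- sort(unique(all_terms), method = "radix")
  structure(v, class = c("vocabulary", "character"))
}

#' Build a per-window TF-IDF document-term matrix
#'
#' Rows are the retained posts of one calendar-quarter window, columns the
#' global vocabulary. Entries are raw term frequency times smoothed inverse
#' document frequency, `idf(t) = ln((1 + n) / (1 + df(t))) + 1`, with both
#' `n` and `df` computed within the window; rows are then L2-normalized.
#' Terms absent from the window give all-zero columns.
#'
#' @param corpus A `tokenized_corpus` restricted to (or containing) the
#'   window.
#' @param vocab The global [build_vocabulary()] result.
#' @param window_id Which window to build; default uses all posts in
#'   `corpus` (useful when `corpus` is already a single window).
#' @return A sparse `dgCMatrix` (posts x terms) with `post_id` rownames;
#'   attribute `window_id`.
#' @export
build_tfidf <- function(corpus, vocab, window_id = NULL) {
  if (!is.null(window_id)) {
    corpus <- corpus[corpus$window_id == window_id, , drop = FALSE]
  } else {
    window_id <- if (nrow(corpus)) corpus$window_id[1] else NA_character_
  }
  n <- nrow(corpus)
  if (n == 0L) stop("window has zero posts: ", window_id)
  m <- length(vocab)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    tt <- corpus$terms[[i]]
    tt <- tt[tt %in% vocab]
    if (length(tt) == 0L) next
    tab <- table(tt)
    ii <- c(ii, rep.int(i, length(tab)))
    jj <- c(jj, match(names(tab), vocab))
    xx <- c(xx, as.numeric(tab))
  }
  tf <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, m),
                             dimnames = list(corpus$post_id, as.character(vocab)))
  df <- Matrix::colSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  A <- tf %*% Matrix::Diagonal(m, idf)
  rn <- sqrt(Matrix::rowSums(A^2))
  rn[rn == 0] <- 1
  A <- Matrix::Diagonal(n, 1 / rn) %*% A
  A <- methods::as(A, "CsparseMatrix")
  dimnames(A) <- list(corpus$post_id, as.character(vocab))
  attr(A, "window_id") <- window_id
  A
}

#' Build TF-IDF matrices for every window
#'
#' @param corpus A `tokenized_corpus`.
#' @param vocab Global vocabulary.
#' @return Named list of matrices, one per window, in chronological
#'   (lexicographic label) order.
#' @export
build_window_matrices <- function(corpus, vocab) {
  wins <- sort(unique(corpus$window_id), method = "radix")
  mats <- lapply(wins, function(w) build_tfidf(corpus, vocab, window_id = w))
  names(mats) <- wins
  mats
}

#' Write a matrix bundle (MTX + sidecar metadata)
#'
#' Serializes a document-term matrix as Matrix Market alongside a JSON of
#' row post ids and a one-term-per-line vocabulary file.
#'
#' @param A Matrix from [build_tfidf()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @export
write_dtm <- function(A, dir, name = attr(A, "window_id")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(A, "generalMatrix"), file.path(dir, paste0(name, ".mtx")))
  jsonlite::write_json(list(window_id = attr(A, "window_id"),
                            post_ids = rownames(A)),
                       file.path(dir, paste0(name, ".rows.json")),
                       auto_unbox = TRUE)
  writeLines(colnames(A), file.path(dir, paste0(name, ".vocab.txt")))
  invisible(dir)
}
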