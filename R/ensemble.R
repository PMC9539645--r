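# Phase 2: the two-layered topic model. First-layer NMF discovers k base
# topics inside every calendar-quarter window; the base topic-term rows are
# stacked into B; second-layer NMF on B yields k' ensemble topics; the
# block-structured document matrix C is projected through the ensemble
# membership W' to give every original post a weight on every ensemble topic.

#' Fit the base (first) topic layer
#'
#' Runs [fit_nmf()] with the same `k` on every window's TF-IDF matrix. Each
#' base model's `H` rows are normalized to unit sum (with the inverse scale
#' folded into `W`), so windows contribute on a comparable scale when
#' stacked.
#'
#' @param matrices Named list of per-window document-term matrices (see
#'   [build_window_matrices()]).
#' @param k Base topic count per window.
#' @param seed Integer seed; window `q` uses `seed + q - 1`.
#' @param ... Passed to [fit_nmf()].
#' @return List of `base_topic_model` objects (fields `window_id`, `W`, `H`,
#'   `k`, `fit`), in window order.
#' @export
fit_base_layer <- function(matrices, k, seed = 1L, ...) {
  stopifnot(length(matrices) >= 1L)
  k <- as.integer(k)
  wins <- names(matrices)
  out <- vector("list", length(matrices))
  for (q in seq_along(matrices)) {
    fit <- tryCatch(
      fit_nmf(matrices[[q]], k = k, seed = seed + q - 1L, ...),
      error = function(e) stop("window ", wins[q], ": ", conditionMessage(e),
                               call. = FALSE)
    )
    rownames(fit$H) <- sprintf("%s.t%d", wins[q], seq_len(k))
    out[[q]] <- structure(
      list(window_id = wins[q], W = fit$W, H = fit$H, k = k, fit = fit),
      class = "base_topic_model")
  }
  names(out) <- wins
  out
}

#' Stack base topic-term matrices into B
#'
#' Concatenates every window's `H` row-wise, windows in order then topics in
#' order, giving the (Q*k) x m base topic-term matrix whose rows are base
#' topics and whose columns stay aligned to the global vocabulary.
#'
#' @param models List of base models from [fit_base_layer()].
#' @return Matrix `B` with a `row_origin` attribute (data.frame of
#'   `window_id`, `topic`).
#' @export
stack_base_topics <- function(models) {
  ms <- vapply(models, function(b) ncol(b$H), integer(1))
  if (length(unique(ms)) != 1L) {
    stop("base models disagree on vocabulary size: ", paste(ms, collapse = ", "))
  }
  B <- do.call(rbind, lapply(models, function(b) b$H))
  origin <- do.call(rbind, lapply(models, function(b) {
    data.frame(window_id = b$window_id, topic = seq_len(b$k),
               stringsAsFactors = FALSE)
  }))
  rownames(origin) <- NULL
  attr(B, "row_origin") <- origin
  B
}

#' Fit the ensemble (second) topic layer
#'
#' Second-layer NMF `B ~ W' H'` over the stacked base topics. Rows of the
#' ensemble topic-term matrix `H'` are normalized to unit sum, the
#' convention under which a term's weight is its share of the topic.
#'
#' @param B Stacked matrix from [stack_base_topics()].
#' @param k_prime Ensemble topic count, `1 <= k_prime <= nrow(B)`.
#' @param seed Integer seed.
#' @param ... Passed to [fit_nmf()].
#' @return `ensemble_topic_model`: `Wp` ((Q*k) x k'), `Hp` (k' x m),
#'   `k_prime`, `row_origin`, `fit`.
#' @export
fit_ensemble <- function(B, k_prime, seed = 1L, ...) {
  fit <- fit_nmf(B, k = k_prime, seed = seed, ...)
  Hp <- fit$H
  rownames(Hp) <- sprintf("et%d", seq_len(k_prime))
  Wp <- fit$W
  colnames(Wp) <- rownames(Hp)
  structure(list(Wp = Wp, Hp = Hp, k_prime = as.integer(k_prime),
                 row_origin = attr(B, "row_origin"), fit = fit),
            class = "ensemble_topic_model")
}

#' Assemble the block document-base-topic matrix C
#'
#' One row per retained post (windows concatenated in model order), Q*k
#' columns. A post's row carries its window's `W` weights in the k columns
#' belonging to that window and zeros elsewhere: each post exists in exactly
#' one window, so the stacked document matrix is block-diagonal by window.
#'
#' @param models List of base models from [fit_base_layer()].
#' @return Sparse matrix `C` (n x Q*k) with post ids as rownames.
#' @export
build_document_block <- function(models) {
  k <- models[[1]]$k
  Q <- length(models)
  blocks <- lapply(seq_along(models), function(q) {
    W <- models[[q]]$W
    left <- (q - 1L) * k
    cbind(matrix(0, nrow(W), left), W, matrix(0, nrow(W), Q * k - left - k))
  })
  C <- do.call(rbind, blocks)
  ids <- unlist(lapply(models, function(b) rownames(b$W)), use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("post appears in more than one window: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(C) <- ids
  colnames(C) <- unlist(lapply(models, function(b) rownames(b$H)), use.names = FALSE)
  C
}

#' Project posts onto ensemble topics
#'
#' Computes the document-ensemble matrix `D = C W'`: every original post's
#' membership weight over every ensemble topic. Nonnegative because both
#' factors are.
#'
#' @param C Block matrix from [build_document_block()].
#' @param ensemble An `ensemble_topic_model`.
#' @return Matrix `D` (n x k') with post ids as rownames.
#' @export
project_documents <- function(C, ensemble) {
  if (ncol(C) != nrow(ensemble$Wp)) {
    stop(sprintf("dimension mismatch: C has %d columns but W' has %d rows",
                 ncol(C), nrow(ensemble$Wp)))
  }
  D <- as.matrix(C %*% ensemble$Wp)
  colnames(D) <- colnames(ensemble$Wp)
  D
}

#' Top descriptive terms of an ensemble topic
#'
#' @param ensemble An `ensemble_topic_model`.
#' @param topic Topic index (1-based).
#' @param n Number of terms (default 10); truncated to the vocabulary size.
#'   Ties in weight are broken lexicographically.
#' @return Character vector of terms, descending weight.
#' @export
top_terms <- function(ensemble, topic, n = 10L) {
  stopifnot(topic >= 1L, topic <= ensemble$k_prime)
  w <- ensemble$Hp[topic, ]
  n <- min(n, length(w))
  ord <- order(-w, names(w), method = "radix")
  names(w)[ord][seq_len(n)]
}

#' Most relevant posts for an ensemble topic
#'
#' @param D Document-ensemble matrix from [project_documents()].
#' @param topic Topic index (1-based).
#' @param m Number of posts (default 20); truncated to the corpus size.
#'   Ties are broken by original post order.
#' @return Character vector of post ids, descending weight.
#' @export
top_posts <- function(D, topic, m = 20L) {
  stopifnot(topic >= 1L, topic <= ncol(D))
  d <- D[, topic]
  m <- min(m, length(d))
  ord <- order(-d, seq_along(d), method = "radix")
  rownames(D)[ord][seq_len(m)]
}

#' Fit the full two-layer topic model
#'
#' Convenience wrapper: base layer, stacking, ensemble layer, document
#' block, and projection in one call.
#'
#' @param matrices Per-window TF-IDF matrices.
#' @param k Base topic count.
#' @param k_prime Ensemble topic count.
#' @param seed Integer seed.
#' @param ... Passed to [fit_nmf()].
#' @return List with `base`, `B`, `ensemble`, `C`, `D`.
#' @export
fit_two_layer <- function(matrices, k, k_prime, seed = 1L, ...) {
  base <- fit_base_layer(matrices, k = k, seed = seed, ...)
  B <- stack_base_topics(base)
  ensemble <- fit_ensemble(B, k_prime = k_prime, seed = seed + length(base), ...)
  C <- build_document_block(base)
  D <- project_documents(C, ensemble)
  list(base = base, B = B, ensemble = ensemble, C = C, D = D)
}

#' @export
print.ensemble_topic_model <- function(x, ...) {
  cat(sprintf("Ensemble topic model: k' = %d topics over %d base topics, %d terms\n",
              x$k_prime, nrow(x$Wp), ncol(x$Hp)))
  invisible(x)
}
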