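# Embedding-based topic coherence and selection of the ensemble topic count.
#
# Coherence of a topic is the mean pairwise cosine similarity of its top-N
# terms in a word-embedding space; a candidate k' is scored by the mean
# coherence over its k' fitted topics and the maximizer (smallest on ties)
# is chosen.

#' Topic coherence of a term set
#'
#' Mean cosine similarity over all unordered pairs of the embedded terms.
#' Terms missing from the embedding vocabulary are skipped (recorded in the
#' `skipped` attribute); with fewer than two embeddable terms the score is 0
#' with a warning.
#'
#' @param terms Character vector (typically the top-N terms of a topic).
#' @param embedding A `word_embedding` (see [train_embedding()]).
#' @return Numeric coherence score in `[-1, 1]`.
#' @export
topic_coherence <- function(terms, embedding) {
  present <- terms[terms %in% rownames(embedding$vectors)]
  skipped <- setdiff(terms, present)
  if (length(present) < 2L) {
    warning("fewer than 2 embeddable terms; coherence set to 0")
    return(structure(0, skipped = skipped))
  }
  V <- embedding$vectors[present, , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  S <- tcrossprod(V)
  score <- mean(S[upper.tri(S)])
  structure(score, skipped = skipped)
}

#' Mean coherence of an ensemble model
#'
#' @param ensemble An `ensemble_topic_model`.
#' @param embedding A `word_embedding`.
#' @param n_terms Top terms per topic entering the coherence (default 10).
#' @return Mean coherence over the model's topics.
#' @export
model_coherence <- function(ensemble, embedding, n_terms = 10L) {
  scores <- vapply(seq_len(ensemble$k_prime), function(t) {
    as.numeric(suppressWarnings(topic_coherence(top_terms(ensemble, t, n_terms),
                                                embedding)))
  }, numeric(1))
  mean(scores)
}

#' Select the ensemble topic count by coherence
#'
#' Fits one ensemble model per candidate `k'`, scores each by mean topic
#' coherence, and picks the maximizer; ties go to the smallest `k'`.
#' Candidates whose fit fails are recorded and skipped.
#'
#' @param B Stacked base topic-term matrix.
#' @param k_prime_range Integer vector of candidate `k'` values (the study
#'   default is `10:20`).
#' @param embedding A `word_embedding` used for coherence.
#' @param n_terms Top terms per topic for coherence (default 10).
#' @param seed Integer seed passed to every candidate fit.
#' @param ... Passed to [fit_ensemble()].
#' @return `coherence_report`: data.frame `report` (`k_prime`, `coherence`,
#'   `ok`, `message`) and `chosen` k'.
#' @export
select_k_prime <- function(B, k_prime_range = 10:20, embedding,
                           n_terms = 10L, seed = 1L, ...) {
  stopifnot(length(k_prime_range) >= 1L)
  rows <- lapply(as.integer(k_prime_range), function(kp) {
    res <- tryCatch({
      ens <- fit_ensemble(B, k_prime = kp, seed = seed, ...)
      list(coh = model_coherence(ens, embedding, n_terms), ok = TRUE, msg = "")
    }, error = function(e) list(coh = NA_real_, ok = FALSE,
                                msg = conditionMessage(e)))
    data.frame(k_prime = kp, coherence = res$coh, ok = res$ok,
               message = res$msg, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  valid <- report[report$ok, , drop = FALSE]
  if (nrow(valid) == 0L) stop("every candidate k' failed to fit")
  best <- valid$k_prime[order(-valid$coherence, valid$k_prime)][1]
  structure(list(report = report, chosen = best), class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat("Coherence-based k' selection\n")
  print(x$report[, c("k_prime", "coherence")], row.names = FALSE)
  cat("chosen k' =", x$chosen, "\n")
  invisible(x)
}
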