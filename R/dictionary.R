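# Phase 4b: assembling the resilience dictionary — for every indicator its
# taxonomy parent and mapped topics, each topic carrying a normalized
# weight (its share of dominant-post mass), its top-10 descriptive terms,
# and 5 embedding neighbors per term.

#' Relative topic weights from the document-ensemble matrix
#'
#' Each post contributes its dominant-topic weight to that topic; the sums
#' are normalized over all topics to percentages. The result is a
#' relative-importance distribution over topics: it sums to 100.
#'
#' @param D Document-ensemble matrix from [project_documents()].
#' @return Named numeric vector, one percentage per ensemble topic (names
#'   are topic indices as character).
#' @export
topic_weights <- function(D) {
  if (is.null(dim(D)) || nrow(D) == 0L) stop("empty corpus: D has no rows")
  dom <- dominant_topics(D)
  dom <- dom[!is.na(dom$dominant_topic), , drop = FALSE]
  if (nrow(dom) == 0L) stop("no post has a nonzero dominant topic")
  sums <- stats::setNames(numeric(ncol(D)), as.character(seq_len(ncol(D))))
  agg <- tapply(dom$dominant_weight, dom$dominant_topic, sum)
  sums[names(agg)] <- agg
  100 * sums / sum(sums)
}

#' Assemble the resilience dictionary
#'
#' Aggregates the taxonomy, the topic-to-indicator mapping, the topic
#' weights, the fitted ensemble topics, and the word embedding into one
#' machine-readable dictionary: per indicator, its parent and its topics,
#' each with label, weight percentage, top descriptive terms, and the
#' nearest embedding neighbors of each term.
#'
#' @param taxonomy A `resilience_taxonomy`.
#' @param map A `topic_indicator_map`.
#' @param weights Named vector from [topic_weights()].
#' @param ensemble An `ensemble_topic_model`.
#' @param embedding A `word_embedding` (or `NULL` to omit synonyms).
#' @param n_words Top terms per topic (default 10).
#' @param n_synonyms Neighbors per term (default 5).
#' @param metadata Optional list (corpus id, dates, config) stored verbatim.
#' @return `resilience_dictionary`: list `entries` (per indicator: `parent`,
#'   `topics`) plus `metadata`.
#' @export
assemble_dictionary <- function(taxonomy, map, weights, ensemble,
                                embedding = NULL, n_words = 10L,
                                n_synonyms = 5L, metadata = list()) {
  labels <- attr(map, "labels")
  entries <- list()
  for (ind in taxonomy$nodes) {
    tids <- as.integer(names(map))[vapply(map, function(s) ind %in% s, logical(1))]
    stale <- tids[tids < 1L | tids > ensemble$k_prime]
    if (length(stale)) {
      message("mapping refers to topics outside the fitted model, ignored: ",
              paste(stale, collapse = ", "))
      tids <- setdiff(tids, stale)
    }
    if (length(tids) == 0L) {
      message("indicator with no mapped topics: ", ind)
    }
    topics <- lapply(sort(tids), function(t) {
      words <- top_terms(ensemble, t, n_words)
      syns <- NULL
      if (!is.null(embedding)) {
        syns <- lapply(words, function(w) {
          as.character(suppressWarnings(synonyms(w, embedding, n_synonyms)))
        })
        names(syns) <- words
      }
      list(topic_id = t,
           label = if (!is.null(labels)) unname(labels[as.character(t)]) else NA_character_,
           weight_pct = unname(weights[as.character(t)]),
           top_words = words,
           synonyms = syns)
    })
    entries[[ind]] <- list(parent = unname(taxonomy$parent[[ind]]),
                           topics = topics)
  }
  structure(list(entries = entries,
                 metadata = c(metadata, list(created = as.character(Sys.Date())))),
            class = "resilience_dictionary")
}

#' Export the dictionary as JSON
#'
#' @param dictionary A `resilience_dictionary`.
#' @param path Output file.
#' @export
write_dictionary_json <- function(dictionary, path) {
  jsonlite::write_json(unclass(dictionary), path, auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Export the dictionary as a flat CSV
#'
#' One row per (indicator, topic) with words and synonyms collapsed to
#' `;`-separated strings.
#'
#' @param dictionary A `resilience_dictionary`.
#' @param path Output file.
#' @export
write_dictionary_csv <- function(dictionary, path) {
  rows <- list()
  for (ind in names(dictionary$entries)) {
    e <- dictionary$entries[[ind]]
    if (length(e$topics) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, parent = ifelse(is.na(e$parent), "", e$parent),
        topic_id = NA_integer_, label = NA_character_, weight_pct = NA_real_,
        top_words = "", synonyms = "", stringsAsFactors = FALSE)
      next
    }
    for (tp in e$topics) {
      syn_flat <- if (is.null(tp$synonyms)) "" else {
        paste(vapply(names(tp$synonyms), function(w) {
          paste0(w, ":", paste(tp$synonyms[[w]], collapse = "|"))
        }, character(1)), collapse = ";")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, parent = ifelse(is.na(e$parent), "", e$parent),
        topic_id = tp$topic_id, label = tp$label,
        weight_pct = tp$weight_pct,
        top_words = paste(tp$top_words, collapse = ";"),
        synonyms = syn_flat, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export the dictionary as Markdown
#'
#' A table in the conventional layout: indicator, parent, topic, weight,
#' top words.
#'
#' @param dictionary A `resilience_dictionary`.
#' @param path Output file.
#' @export
write_dictionary_md <- function(dictionary, path) {
  lines <- c("# Resilience dictionary", "",
             "| Indicator | Parent | Topic | Weight (%) | Topic words |",
             "|---|---|---|---|---|")
  for (ind in names(dictionary$entries)) {
    e <- dictionary$entries[[ind]]
    parent <- ifelse(is.na(e$parent), "—", e$parent)
    if (length(e$topics) == 0L) {
      lines <- c(lines, sprintf("| %s | %s | — | — | — |", ind, parent))
    }
    for (tp in e$topics) {
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %.1f | %s |", ind, parent,
        ifelse(is.na(tp$label), paste0("topic ", tp$topic_id), tp$label),
        tp$weight_pct, paste(tp$top_words, collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.resilience_dictionary <- function(x, ...) {
  cat("Resilience dictionary:", length(x$entries), "indicators\n")
  for (ind in names(x$entries)) {
    e <- x$entries[[ind]]
    cat(sprintf("  %s (parent: %s, %d topic(s))\n", ind,
                ifelse(is.na(e$parent), "none", e$parent), length(e$topics)))
  }
  invisible(x)
}
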