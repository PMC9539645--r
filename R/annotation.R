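# Phase 3: annotating posts with their dominant ensemble topic and the
# resilience indicators a human coding maps that topic to, and measuring
# per-quarter indicator prevalence.

#' The five resilience indicators
#'
#' Fixed by the strengths-based resilience framework: access to social
#' networks and support (social capital), group/place belonging, learning,
#' adaptive capacity, and self-efficacy.
#'
#' @export
RESILIENCE_INDICATORS <- c("social_capital", "belonging", "learning",
                           "adaptive_capacity", "self_efficacy")

#' Dominant ensemble topic of each post
#'
#' Argmax over each row of the document-ensemble matrix `D`. Ties are broken
#' by the lowest topic index (the count of tied rows is reported via
#' `message`); all-zero rows get the sentinel `NA` ("no topic") and are
#' excluded from prevalence numerators downstream.
#'
#' @param D Matrix from [project_documents()].
#' @return data.frame with `post_id`, `dominant_topic` (integer, `NA` for
#'   all-zero rows) and `dominant_weight`.
#' @export
dominant_topics <- function(D) {
  stopifnot(is.matrix(D), ncol(D) >= 1L)
  idx <- max.col(D, ties.method = "first")
  w <- D[cbind(seq_len(nrow(D)), idx)]
  n_tied <- sum(rowSums(D == w) > 1L & w > 0)
  if (n_tied > 0L) message(n_tied, " post(s) had tied dominant-topic weights; lowest index kept")
  zero <- w <= 0
  idx[zero] <- NA_integer_
  w[zero] <- NA_real_
  data.frame(post_id = rownames(D), dominant_topic = idx,
             dominant_weight = w, stringsAsFactors = FALSE)
}

#' Read a topic-to-indicator mapping
#'
#' The mapping is the reviewed output of the qualitative coding step: for
#' each ensemble topic, a label and the set of indicators it realizes
#' (possibly empty, possibly several).
#'
#' @param path YAML or JSON file with entries `topic` (integer id),
#'   optional `label`, and `indicators` (list of indicator names).
#' @return A `topic_indicator_map`: named list `topic id -> character
#'   vector of indicators`, with a `labels` attribute.
#' @export
read_topic_map <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  entries <- if (!is.null(raw$topics)) raw$topics else raw
  ids <- vapply(entries, function(e) as.integer(e$topic), integer(1))
  map <- lapply(entries, function(e) as.character(unlist(e$indicators)))
  labels <- vapply(entries, function(e) {
    if (is.null(e$label)) NA_character_ else as.character(e$label)
  }, character(1))
  topic_indicator_map(stats::setNames(map, ids), stats::setNames(labels, ids))
}

#' Construct a topic-to-indicator mapping in code
#'
#' @param map Named list: names are topic ids (integers as names), values
#'   character vectors of indicator names (possibly empty).
#' @param labels Optional named character vector of topic labels.
#' @return A `topic_indicator_map`.
#' @export
topic_indicator_map <- function(map, labels = NULL) {
  bad <- setdiff(unlist(map, use.names = FALSE), RESILIENCE_INDICATORS)
  if (length(bad)) {
    stop("unknown indicator name(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(map, labels = labels, class = "topic_indicator_map")
}

#' Annotate posts with dominant topics and indicators
#'
#' Each post inherits the indicator set of its dominant topic only. Topics
#' absent from the mapping yield empty indicator sets (reported via
#' `message`).
#'
#' @param D Document-ensemble matrix.
#' @param map A `topic_indicator_map`.
#' @param windows Character vector of window ids aligned with the rows of
#'   `D` (or a `tokenized_corpus` to take them from).
#' @return data.frame `annotated_posts`: `post_id`, `window_id`,
#'   `dominant_topic`, `dominant_weight`, list-column `indicators`.
#' @export
annotate <- function(D, map, windows) {
  if (is.data.frame(windows)) {
    ix <- match(rownames(D), windows$post_id)
    if (anyNA(ix)) stop("D rows and corpus post ids are misaligned")
    windows <- windows$window_id[ix]
  }
  if (length(windows) != nrow(D)) {
    stop("windows must align with the rows of D")
  }
  dom <- dominant_topics(D)
  unmapped <- setdiff(unique(dom$dominant_topic[!is.na(dom$dominant_topic)]),
                      as.integer(names(map)))
  if (length(unmapped)) {
    message("topic(s) without an indicator mapping: ",
            paste(sort(unmapped), collapse = ", "))
  }
  inds <- lapply(dom$dominant_topic, function(t) {
    if (is.na(t)) return(character(0))
    hit <- map[[as.character(t)]]
    if (is.null(hit)) character(0) else hit
  })
  out <- data.frame(post_id = dom$post_id, window_id = windows,
                    dominant_topic = dom$dominant_topic,
                    dominant_weight = dom$dominant_weight,
                    stringsAsFactors = FALSE)
  out$indicators <- inds
  class(out) <- c("annotated_posts", "data.frame")
  out
}

#' Indicator prevalence per window
#'
#' For every window and indicator, the proportion of that window's retained
#' posts whose dominant topic maps to the indicator. The denominator is all
#' retained posts in the window (including posts with unmapped or no-topic
#' annotations), so proportions are comparable across windows; a post with
#' several indicators counts once for each, so indicator proportions can sum
#' above one within a window.
#'
#' @param annotated An `annotated_posts` data.frame.
#' @param indicators Indicator universe (default the five framework names).
#' @return Tidy data.frame: `window_id`, `indicator`, `n`, `total`,
#'   `proportion` — long form suitable for streamgraph rendering.
#' @export
prevalence <- function(annotated, indicators = RESILIENCE_INDICATORS) {
  wins <- sort(unique(annotated$window_id), method = "radix")
  out <- expand.grid(window_id = wins, indicator = indicators,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$window_id, out$indicator), , drop = FALSE]
  rownames(out) <- NULL
  totals <- table(annotated$window_id)
  out$total <- as.integer(totals[out$window_id])
  out$n <- mapply(function(w, ind) {
    rows <- annotated$window_id == w
    sum(vapply(annotated$indicators[rows], function(s) ind %in% s, logical(1)))
  }, out$window_id, out$indicator)
  empty <- out$total == 0L | is.na(out$total)
  if (any(empty)) warning("empty window(s); proportions set to 0")
  out$proportion <- ifelse(empty, 0, out$n / out$total)
  out[, c("window_id", "indicator", "n", "total", "proportion")]
}

#' Flatten annotations for CSV export
#'
#' @param annotated An `annotated_posts` data.frame.
#' @return data.frame with `indicators` collapsed to a `;`-separated string.
#' @export
flatten_annotations <- function(annotated) {
  out <- annotated[, c("post_id", "window_id", "dominant_topic", "dominant_weight")]
  out$indicators <- vapply(annotated$indicators, paste, character(1), collapse = ";")
  out
}
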