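# Phase 1: preprocessing of forum posts.
#
# Raw posts (post_id, optional author_id, timestamp, text) are deidentified,
# sentence-split, tokenized, stopword-filtered, lemmatized, pruned when too
# short, and assigned to calendar-quarter windows.

USER_PLACEHOLDER <- "[USER]"

#' Preprocessing configuration
#'
#' @param min_terms Minimum number of terms a post must retain to enter topic
#'   modeling; posts with fewer are removed. Default 5.
#' @param stopwords Character vector of stopwords, dropped case-insensitively.
#' @param allowed_pos Part-of-speech tags kept when a `pos_lexicon` is
#'   supplied; default keeps content words (nouns, verbs, adjectives,
#'   adverbs).
#' @param pos_lexicon Optional named character vector mapping lowercase terms
#'   to POS tags (e.g. `c(cat = "NOUN")`). Tokens whose tag is not in
#'   `allowed_pos` are dropped; tokens absent from the lexicon are kept.
#'   `NULL` (default) disables POS filtering.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_terms = 5L,
                              stopwords = default_stopwords(),
                              allowed_pos = c("NOUN", "VERB", "ADJ", "ADV"),
                              pos_lexicon = NULL) {
  min_terms <- as.integer(min_terms)
  stopifnot(length(min_terms) == 1L, !is.na(min_terms), min_terms >= 1L)
  if (!is.null(pos_lexicon) && is.null(names(pos_lexicon))) {
    stop("pos_lexicon must be a named character vector (term -> tag)")
  }
  structure(
    list(min_terms = min_terms,
         stopwords = tolower(stopwords),
         allowed_pos = toupper(allowed_pos),
         pos_lexicon = pos_lexicon),
    class = "preprocess_config"
  )
}

#' Remove author identifiers from a post
#'
#' Blanks the `author_id` field and replaces every occurrence of the author
#' identifier inside the post text (with or without a leading `@`) by the
#' fixed placeholder `[USER]`. A no-op when the post carries no identifier.
#'
#' @param post A list or one-row data.frame with at least `text`, and
#'   optionally `author_id`.
#' @return The post with `author_id` set to `NA` and mentions replaced.
#' @export
deidentify <- function(post) {
  aid <- post$author_id
  if (!is.null(aid) && length(aid) == 1L && !is.na(aid) && nzchar(aid)) {
    pat <- paste0("@?", .regex_escape(aid))
    post$text <- gsub(pat, USER_PLACEHOLDER, post$text, ignore.case = TRUE)
  }
  post$author_id <- NA_character_
  post
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Tokenize and lemmatize a post
#'
#' Splits the text into sentences, extracts word tokens, lowercases them,
#' drops stopwords (and, when a POS lexicon is configured, tokens with a
#' disallowed tag), and lemmatizes the survivors. Token order is preserved.
#'
#' @param post A deidentified post (list with `post_id`, `timestamp`, `text`).
#' @param config A [preprocess_config()].
#' @return A list with `post_id`, `window_id` and `terms` (character vector,
#'   possibly empty).
#' @export
tokenize <- function(post, config = preprocess_config()) {
  toks <- tokenize_text(post$text, config)
  list(post_id = post$post_id,
       window_id = assign_window(post),
       terms = toks)
}

#' @rdname tokenize
#' @param text Character scalar of raw text.
#' @export
tokenize_text <- function(text, config = preprocess_config()) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  # sentence split, then word tokens; apostrophes are dropped inside words
  # so contractions match the stopword list ("don't" -> "dont")
  sentences <- unlist(strsplit(text, "[.!?]+\\s*"))
  toks <- unlist(regmatches(sentences, gregexpr("[A-Za-z0-9']+", sentences)))
  if (length(toks) == 0L) return(character(0))
  toks <- tolower(gsub("'", "", toks))
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% config$stopwords]
  if (!is.null(config$pos_lexicon)) {
    tags <- config$pos_lexicon[toks]
    keep <- is.na(tags) | toupper(tags) %in% config$allowed_pos
    toks <- toks[keep]
  }
  toks <- lemmatize(toks)
  toks <- toks[!toks %in% config$stopwords]  # lemma may itself be a stopword
  toks[nzchar(toks)]
}

#' Remove posts that are too short for topic modeling
#'
#' Retains exactly the posts with at least `min_terms` terms, preserving the
#' original order. Idempotent.
#'
#' @param posts A `tokenized_corpus` (or plain list of tokenized posts).
#' @param min_terms Integer threshold; posts with fewer terms are removed.
#' @return The retained posts, same class as the input.
#' @export
filter_short <- function(posts, min_terms = 5L) {
  if (inherits(posts, "tokenized_corpus")) {
    keep <- lengths(posts$terms) >= min_terms
    out <- posts[keep, , drop = FALSE]
    class(out) <- class(posts)
    return(out)
  }
  posts[vapply(posts, function(p) length(p$terms), integer(1)) >= min_terms]
}

#' Assign a post to its calendar-quarter window
#'
#' Quarters follow the calendar: Jan-Mar is Q1, Apr-Jun Q2, Jul-Sep Q3,
#' Oct-Dec Q4; the label is `YYYY-Qn`.
#'
#' @param post A post (list with `timestamp` and `post_id`), or a character
#'   timestamp.
#' @return Window label such as `"2018-Q3"`.
#' @export
#' @examples
#' assign_window(list(post_id = "p1", timestamp = "2018-07-01"))
assign_window <- function(post) {
  ts <- if (is.list(post)) post$timestamp else post
  d <- tryCatch(as.Date(substr(as.character(ts), 1L, 10L)),
                error = function(e) as.Date(NA))
  if (any(is.na(d))) {
    bad <- if (is.list(post)) post$post_id else ts
    stop("unparseable timestamp for post: ", paste(bad[is.na(d)], collapse = ", "))
  }
  m <- as.integer(format(d, "%m"))
  sprintf("%s-Q%d", format(d, "%Y"), (m - 1L) %/% 3L + 1L)
}

#' Preprocess a raw corpus end to end
#'
#' Applies [deidentify()], [tokenize()], and [filter_short()] to every post
#' and assigns quarter windows, producing the tokenized corpus consumed by
#' the matrix-building stage together with a summary report.
#'
#' @param posts data.frame with columns `post_id`, `timestamp`, `text` and
#'   optionally `author_id`.
#' @param config A [preprocess_config()].
#' @return A `tokenized_corpus`: data.frame with columns `post_id`,
#'   `window_id`, and list-column `terms`; attributes carry the report.
#' @export
preprocess_corpus <- function(posts, config = preprocess_config()) {
  stopifnot(is.data.frame(posts), all(c("post_id", "timestamp", "text") %in% names(posts)))
  if (anyDuplicated(posts$post_id)) stop("post_id values must be unique")
  n_in <- nrow(posts)
  has_author <- "author_id" %in% names(posts)
  terms <- vector("list", n_in)
  windows <- character(n_in)
  for (i in seq_len(n_in)) {
    p <- list(post_id = posts$post_id[i],
              author_id = if (has_author) posts$author_id[i] else NA_character_,
              timestamp = posts$timestamp[i],
              text = posts$text[i])
    p <- deidentify(p)
    windows[i] <- assign_window(p)
    terms[[i]] <- tokenize_text(p$text, config)
  }
  corpus <- data.frame(post_id = as.character(posts$post_id),
                       window_id = windows, stringsAsFactors = FALSE)
  corpus$terms <- terms
  class(corpus) <- c("tokenized_corpus", "data.frame")
  retained <- filter_short(corpus, config$min_terms)
  attr(retained, "report") <- preprocess_report(n_in, nrow(retained),
                                                sum(lengths(retained$terms)))
  retained
}

#' Preprocessing summary report
#'
#' Retention arithmetic for a filtered corpus: counts of posts in and out and
#' the retained/removed percentages (two decimals, as conventionally
#' reported).
#'
#' @param n_input Number of raw posts.
#' @param n_retained Number of posts surviving the length filter.
#' @param n_terms Total term tokens across retained posts (optional).
#' @return A list with counts and `retained_pct` / `removed_pct`.
#' @export
#' @examples
#' preprocess_report(70179, 48819)$retained_pct  # 69.56
preprocess_report <- function(n_input, n_retained, n_terms = NA_integer_) {
  stopifnot(n_retained <= n_input)
  list(n_input = n_input,
       n_retained = n_retained,
       n_removed = n_input - n_retained,
       n_terms = n_terms,
       retained_pct = round(100 * n_retained / n_input, 2),
       removed_pct = round(100 * (n_input - n_retained) / n_input, 2))
}

#' Read a raw corpus from CSV or JSONL
#'
#' @param path File path; `.jsonl`/`.ndjson` files are read line-wise as JSON
#'   records, anything else as CSV with a header. Required fields: `post_id`,
#'   `timestamp`, `text`; `author_id` optional.
#' @return data.frame of raw posts.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(post_id = as.character(r$post_id),
                 author_id = if (is.null(r$author_id)) NA_character_ else as.character(r$author_id),
                 timestamp = as.character(r$timestamp),
                 text = as.character(r$text),
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  need <- setdiff(c("post_id", "timestamp", "text"), names(df))
  if (length(need)) stop("corpus file missing fields: ", paste(need, collapse = ", "))
  if (!"author_id" %in% names(df)) df$author_id <- NA_character_
  df
}

#' Write a tokenized corpus as JSONL
#'
#' One JSON record per line with `post_id`, `window_id`, `terms`.
#'
#' @param corpus A `tokenized_corpus`.
#' @param path Output file path.
#' @export
write_tokenized <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(
      list(post_id = corpus$post_id[i],
           window_id = corpus$window_id[i],
           terms = corpus$terms[[i]]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("Tokenized corpus: %d posts, %d windows (%s), %d term tokens\n",
              nrow(x), length(unique(x$window_id)),
              paste(sort(unique(x$window_id)), collapse = ", "),
              sum(lengths(x$terms))))
  invisible(x)
}
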