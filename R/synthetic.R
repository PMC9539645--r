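# Synthetic forum corpora with known ground truth. Documents are bags of
# pseudo-words drawn from planted topic-term distributions; some topics are
# shared by every calendar quarter (persistent themes), others belong to a
# single quarter (periodic themes). Each document's true dominant topic
# determines its true resilience indicators, and the indicator design is
# nested so the planted subsumption taxonomy is known exactly:
# social_capital posts are always belonging posts, adaptive_capacity posts
# always learning posts, and self_efficacy posts carry no other indicator.

#' Configuration of the synthetic corpus generator
#'
#' Defaults are the package's reference simulation conditions: four
#' quarters from 2018-Q3, 500 posts per quarter, 3 shared + 2
#' window-specific topics per window (so a matched base-topic count of 5),
#' disjoint 30-term topic supports over a pseudo-word vocabulary plus 50
#' background terms, document lengths around 30 terms, 10% deliberately
#' short posts to exercise the length filter, a dominant-topic mixture
#' weight of 0.75, and 8 planted synonym pairs.
#'
#' @param windows Number of calendar-quarter windows Q.
#' @param docs_per_window Posts generated per window.
#' @param n_shared_topics Topics active in every window.
#' @param n_window_topics Additional topics specific to each window.
#' @param terms_per_topic Size of each topic's (disjoint) term support.
#' @param background_terms Terms shared by all topics at low mass.
#' @param vocab_size Optional total vocabulary size; must be at least the
#'   required size (topic supports + background + synonym terms), extra
#'   terms become background. `NULL` uses exactly the required size.
#' @param doc_length_mean Mean document length (Poisson).
#' @param doc_length_min Minimum length of a regular (non-short) document.
#' @param short_post_fraction Fraction of posts forced below 5 terms.
#' @param dominant_weight Mixture weight of a document's dominant topic.
#' @param n_synonym_pairs Planted pairs of interchangeable terms.
#' @param start_quarter First window label, e.g. `"2018-Q3"`.
#' @param seed Integer seed; identical seed gives a byte-identical corpus.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(windows = 4L, docs_per_window = 500L,
                             n_shared_topics = 3L, n_window_topics = 2L,
                             terms_per_topic = 30L, background_terms = 50L,
                             vocab_size = NULL, doc_length_mean = 30,
                             doc_length_min = 6L, short_post_fraction = 0.1,
                             dominant_weight = 0.75, n_synonym_pairs = 8L,
                             start_quarter = "2018-Q3", seed = 42L) {
  cfg <- list(windows = as.integer(windows),
              docs_per_window = as.integer(docs_per_window),
              n_shared_topics = as.integer(n_shared_topics),
              n_window_topics = as.integer(n_window_topics),
              terms_per_topic = as.integer(terms_per_topic),
              background_terms = as.integer(background_terms),
              vocab_size = if (is.null(vocab_size)) NULL else as.integer(vocab_size),
              doc_length_mean = doc_length_mean,
              doc_length_min = as.integer(doc_length_min),
              short_post_fraction = short_post_fraction,
              dominant_weight = dominant_weight,
              n_synonym_pairs = as.integer(n_synonym_pairs),
              start_quarter = start_quarter,
              seed = as.integer(seed))
  n_topics <- cfg$n_shared_topics + cfg$windows * cfg$n_window_topics
  required <- n_topics * cfg$terms_per_topic + cfg$background_terms +
    4L * cfg$n_synonym_pairs  # each pair: two members + two collocates
  if (!is.null(cfg$vocab_size) && cfg$vocab_size < required) {
    stop(sprintf("vocab_size %d smaller than required %d (topics x support + background + synonyms)",
                 cfg$vocab_size, required))
  }
  cfg$required_vocab <- required
  structure(cfg, class = "synthetic_config")
}

.insert_after <- function(x, pos, values) {
  out <- character(length(x) + length(pos))
  j <- sort(pos)
  idx <- seq_along(x) + findInterval(seq_along(x), j + 1e-9)
  out[idx] <- x
  out[j + seq_along(j)] <- values[order(pos)]
  out
}

.quarter_seq <- function(start, n) {
  y <- as.integer(substr(start, 1, 4))
  q <- as.integer(substr(start, 7, 7))
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- sprintf("%d-Q%d", y, q)
    q <- q + 1L
    if (q == 5L) { q <- 1L; y <- y + 1L }
  }
  out
}

.quarter_dates <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 7, 7))
  first <- as.Date(sprintf("%d-%02d-01", y, (q - 1L) * 3L + 1L))
  last <- seq(first, by = "3 months", length.out = 2)[2] - 1
  c(first, last)
}

#' Generate a synthetic forum corpus with ground truth
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_corpus` with `posts` (raw-post
#'   data.frame: `post_id`, `author_id`, `timestamp`, `text`) and `truth`
#'   (planted topics and their ordered term supports, topic-to-indicator
#'   design, per-post truth, exact per-window prevalences over retained
#'   posts, the planted taxonomy, and the synonym pairs).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  cfg <- config
  old <- .Random.seed_get()
  set.seed(cfg$seed)
  on.exit(.Random.seed_restore(old))

  wins <- .quarter_seq(cfg$start_quarter, cfg$windows)
  topic_ids <- c(sprintf("S%d", seq_len(cfg$n_shared_topics)),
                 unlist(lapply(seq_len(cfg$windows), function(q)
                   sprintf("U%d.%d", q, seq_len(cfg$n_window_topics)))))
  n_topics <- length(topic_ids)

  # vocabulary: disjoint topic supports, background, synonym-pair terms
  topic_terms <- lapply(seq_len(n_topics) - 1L, function(i) {
    sprintf("w%04d", i * cfg$terms_per_topic + seq_len(cfg$terms_per_topic))
  })
  names(topic_terms) <- topic_ids
  n_bg <- cfg$background_terms +
    if (!is.null(cfg$vocab_size)) cfg$vocab_size - cfg$required_vocab else 0L
  bg_terms <- sprintf("b%03d", seq_len(n_bg))
  syn_a <- sprintf("syn%02da", seq_len(cfg$n_synonym_pairs))
  syn_b <- sprintf("syn%02db", seq_len(cfg$n_synonym_pairs))
  # pairs are hosted by the shared (persistent) topics: embedding-based
  # synonymy needs corpus frequencies a single-quarter topic cannot provide
  syn_topic <- topic_ids[((seq_len(cfg$n_synonym_pairs) - 1L) %%
                            cfg$n_shared_topics) + 1L]
  # each pair owns two collocate terms; a pair token is always followed by
  # one of them, so the two pair members share a local collocational
  # signature no other term has (how synonyms look distributionally)
  syn_col <- cbind(sprintf("col%02dx", seq_len(cfg$n_synonym_pairs)),
                   sprintf("col%02dy", seq_len(cfg$n_synonym_pairs)))
  pair_of <- stats::setNames(rep(seq_len(cfg$n_synonym_pairs), 2L),
                             c(syn_a, syn_b))

  # per-topic term distribution: geometric decay over the support, plus, for
  # topics hosting a planted synonym pair, a small equal mass on each pair
  # term (interchangeable low-frequency members of the topic, so the two
  # have identical context distributions by construction); a uniform
  # background absorbs 10% of every token draw
  decay <- 0.9^(seq_len(cfg$terms_per_topic) - 1L)
  syn_mass <- 0.05  # per pair, split over its two terms
  topic_dist <- lapply(topic_ids, function(tid) {
    pr <- which(syn_topic == tid)
    terms <- topic_terms[[tid]]
    probs <- decay / sum(decay)
    if (length(pr)) {
      terms <- c(terms, rbind(syn_a[pr], syn_b[pr]))
      probs <- c(probs * (1 - syn_mass * length(pr)),
                 rep(syn_mass / 2, 2L * length(pr)))
    }
    list(terms = terms, probs = probs)
  })
  names(topic_dist) <- topic_ids

  # indicator design: nested by construction
  ind_map <- stats::setNames(vector("list", n_topics), topic_ids)
  for (i in seq_len(n_topics)) {
    tid <- topic_ids[i]
    if (grepl("^S", tid)) {
      j <- as.integer(substr(tid, 2, 10))
      ind_map[[tid]] <- switch(((j - 1L) %% 3L) + 1L,
                               c("belonging", "social_capital"),
                               c("learning", "adaptive_capacity"),
                               "self_efficacy")
    } else {
      k <- as.integer(sub("^U\\d+\\.", "", tid))
      ind_map[[tid]] <- if (k %% 2L == 1L) "belonging" else "learning"
    }
  }

  window_topics <- lapply(seq_len(cfg$windows), function(q) {
    c(sprintf("S%d", seq_len(cfg$n_shared_topics)),
      sprintf("U%d.%d", q, seq_len(cfg$n_window_topics)))
  })

  n_total <- cfg$windows * cfg$docs_per_window
  post_id <- sprintf("p%05d", seq_len(n_total))
  rows <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  i <- 0L
  for (q in seq_len(cfg$windows)) {
    active <- window_topics[[q]]
    dates <- .quarter_dates(wins[q])
    for (d in seq_len(cfg$docs_per_window)) {
      i <- i + 1L
      dom <- sample(active, 1L)
      short <- stats::runif(1) < cfg$short_post_fraction
      len <- if (short) sample(1:4, 1L) else {
        max(cfg$doc_length_min, stats::rpois(1, cfg$doc_length_mean))
      }
      # token-level mixture: dominant topic vs the other active topics,
      # with a 10% background draw at every token
      others <- setdiff(active, dom)
      tok_topics <- if (length(others) == 0L) rep(dom, len) else {
        ifelse(stats::runif(len) < cfg$dominant_weight, dom,
               others[sample.int(length(others), len, replace = TRUE)])
      }
      toks <- vapply(tok_topics, function(tp) {
        if (stats::runif(1) < 0.1) return(sample(bg_terms, 1L))
        td <- topic_dist[[tp]]
        sample(td$terms, 1L, prob = td$probs)
      }, character(1))
      hits <- which(toks %in% names(pair_of))
      if (length(hits)) {
        cols <- vapply(toks[hits], function(w)
          syn_col[pair_of[[w]], sample(1:2, 1L)], character(1))
        toks <- .insert_after(toks, hits, cols)
      }
      ts <- as.Date(sample(as.integer(dates[1]):as.integer(dates[2]), 1L),
                    origin = "1970-01-01")
      rows[[i]] <- data.frame(
        post_id = post_id[i],
        author_id = sprintf("user%03d", sample.int(200L, 1L)),
        timestamp = format(ts, "%Y-%m-%d"),
        text = paste(toks, collapse = " "),
        stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        post_id = post_id[i], window_id = wins[q], topic = dom,
        n_terms = length(toks), retained = length(toks) >= 5L,
        stringsAsFactors = FALSE)
    }
  }
  posts <- do.call(rbind, rows)
  post_truth <- do.call(rbind, truth_rows)
  post_truth$indicators <- ind_map[post_truth$topic]

  # exact bookkeeping prevalences over retained posts
  ret <- post_truth[post_truth$retained, , drop = FALSE]
  prev <- expand.grid(window_id = wins, indicator = RESILIENCE_INDICATORS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prev$proportion <- mapply(function(w, ind) {
    rows <- ret$window_id == w
    sum(vapply(ret$indicators[rows], function(s) ind %in% s, logical(1))) /
      sum(rows)
  }, prev$window_id, prev$indicator)

  taxonomy_truth <- stats::setNames(rep(NA_character_, 5), RESILIENCE_INDICATORS)
  taxonomy_truth["social_capital"] <- "belonging"
  taxonomy_truth["adaptive_capacity"] <- "learning"

  structure(list(
    posts = posts,
    truth = list(
      windows = wins,
      topic_ids = topic_ids,
      topic_terms = topic_terms,
      topic_indicators = ind_map,
      window_topics = stats::setNames(window_topics, wins),
      post_truth = post_truth,
      prevalence = prev,
      taxonomy = taxonomy_truth,
      synonym_pairs = data.frame(a = syn_a, b = syn_b, topic = syn_topic,
                                 stringsAsFactors = FALSE),
      n_short = sum(!post_truth$retained),
      config = cfg)),
    class = "synthetic_corpus")
}

#' Score pipeline recovery against the planted ground truth
#'
#' Matches every planted topic to its best-overlapping fitted ensemble
#' topic, builds the induced topic-to-indicator mapping, annotates the
#' corpus, and compares prevalence, taxonomy, and (optionally) synonym
#' ranking against the generator's bookkeeping.
#'
#' @param model Output of [fit_two_layer()] run on the generated corpus.
#' @param corpus The retained `tokenized_corpus` the model was fitted on.
#' @param truth The `truth` element of [generate_corpus()]'s result.
#' @param embedding Optional `word_embedding` for the synonym check.
#' @return List: `topic_overlap` (per planted topic, top-10 overlap with its
#'   best fitted topic), `mean_topic_overlap`, `prevalence` (data.frame with
#'   absolute errors), `max_prevalence_error`, `taxonomy`,
#'   `taxonomy_match`, `synonym_top1_rate` (`NA` without an embedding).
#' @export
evaluate_recovery <- function(model, corpus, truth, embedding = NULL) {
  if (!all(rownames(model$D) %in% truth$post_truth$post_id)) {
    stop("model posts do not match the ground-truth corpus")
  }
  ens <- model$ensemble
  fitted_top <- lapply(seq_len(ens$k_prime), function(t) top_terms(ens, t, 10L))
  planted_top <- lapply(truth$topic_terms, function(s) s[seq_len(min(10L, length(s)))])

  overlap <- vapply(planted_top, function(pt) {
    max(vapply(fitted_top, function(ft) length(intersect(ft, pt)) / 10, numeric(1)))
  }, numeric(1))

  # fitted topic -> indicators of its best-matching planted topic
  map <- lapply(seq_len(ens$k_prime), function(t) {
    ovl <- vapply(planted_top, function(pt)
      length(intersect(fitted_top[[t]], pt)), numeric(1))
    truth$topic_indicators[[names(which.max(ovl))]]
  })
  map <- topic_indicator_map(stats::setNames(map, seq_len(ens$k_prime)))

  ann <- suppressMessages(annotate(model$D, map, corpus))
  prev <- prevalence(ann)
  key <- paste(prev$window_id, prev$indicator)
  tkey <- paste(truth$prevalence$window_id, truth$prevalence$indicator)
  prev$true_proportion <- truth$prevalence$proportion[match(key, tkey)]
  prev$abs_error <- abs(prev$proportion - prev$true_proportion)

  sets <- collect_post_sets(ann)
  tax <- suppressMessages(infer_taxonomy(sets, mode = "strict"))
  tax_match <- identical(unname(tax$parent[names(truth$taxonomy)]),
                         unname(truth$taxonomy))

  syn_rate <- NA_real_
  if (!is.null(embedding)) {
    pairs <- truth$synonym_pairs
    hits <- c(
      vapply(seq_len(nrow(pairs)), function(i) {
        s <- suppressWarnings(synonyms(pairs$a[i], embedding, 1L))
        length(s) == 1L && s == pairs$b[i]
      }, logical(1)),
      vapply(seq_len(nrow(pairs)), function(i) {
        s <- suppressWarnings(synonyms(pairs$b[i], embedding, 1L))
        length(s) == 1L && s == pairs$a[i]
      }, logical(1)))
    syn_rate <- mean(hits)
  }

  list(topic_overlap = overlap,
       mean_topic_overlap = mean(overlap),
       prevalence = prev,
       max_prevalence_error = max(prev$abs_error),
       taxonomy = tax,
       taxonomy_match = tax_match,
       synonym_top1_rate = syn_rate)
}

#' Write a synthetic corpus in the raw-post CSV format
#'
#' @param corpus A `synthetic_corpus`.
#' @param path CSV output path; ground truth goes to `<path>.truth.json`.
#' @export
write_synthetic <- function(corpus, path) {
  utils::write.csv(corpus$posts, path, row.names = FALSE)
  truth <- corpus$truth
  truth$post_truth$indicators <- NULL
  jsonlite::write_json(
    list(windows = truth$windows, topic_ids = truth$topic_ids,
         topic_terms = truth$topic_terms,
         topic_indicators = truth$topic_indicators,
         prevalence = truth$prevalence, taxonomy = as.list(truth$taxonomy),
         synonym_pairs = truth$synonym_pairs, n_short = truth$n_short),
    paste0(path, ".truth.json"), auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
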