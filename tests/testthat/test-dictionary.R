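test_that("topic weights are dominant-weight shares in percent", {
  D <- matrix(c(0.9, 0.7), 2, 1, dimnames = list(c("p1", "p2"), NULL))
  expect_equal(unname(topic_weights(D)), 100)

  D <- rbind(c(0.6, 0.1), c(0.2, 0.4))
  rownames(D) <- c("p1", "p2")
  expect_equal(unname(topic_weights(D)), c(60, 40))

  # 5-post, 3-topic toy against hand-computed shares
  D <- rbind(c(0.5, 0.2, 0.1),
             c(0.1, 0.4, 0.2),
             c(0.0, 0.0, 0.3),
             c(0.6, 0.1, 0.1),
             c(0.1, 0.1, 0.2))
  rownames(D) <- sprintf("p%d", 1:5)
  tot <- 0.5 + 0.4 + 0.3 + 0.6 + 0.2
  expect_equal(unname(topic_weights(D)),
               100 * c(1.1, 0.4, 0.5) / tot, tolerance = 1e-12)
  expect_equal(sum(topic_weights(D)), 100, tolerance = 1e-9)
  expect_error(topic_weights(matrix(numeric(0), 0, 2)), "empty")
})

test_that("dictionary assembly is consistent with taxonomy and mapping", {
  Hp <- rbind(c(a = .5, b = .3, c = .2, d = 0),
              c(a = 0, b = .1, c = .4, d = .5),
              c(a = .25, b = .25, c = .25, d = .25))
  ens <- structure(list(Wp = diag(3), Hp = Hp, k_prime = 3L),
                   class = "ensemble_topic_model")
  D <- rbind(c(.9, 0, .1), c(.1, .8, 0), c(0, .2, .6), c(.7, .1, 0))
  rownames(D) <- sprintf("p%d", 1:4)
  map <- topic_indicator_map(
    list("1" = c("belonging", "social_capital"), "2" = "belonging",
         "3" = "self_efficacy"),
    labels = c("1" = "Gratitude", "2" = "Welcoming", "3" = "Knowing"))
  ann <- annotate(D, map, rep("2018-Q3", 4))
  tax <- suppressMessages(infer_taxonomy(collect_post_sets(ann)))
  w <- topic_weights(D)
  V <- matrix(rnorm(4 * 5), 4, 5, dimnames = list(c("a", "b", "c", "d"), NULL))
  dict <- suppressMessages(assemble_dictionary(tax, map, w, ens,
                                               word_embedding(V),
                                               n_words = 3, n_synonyms = 2))

  # parents come from the taxonomy (social_capital posts nest in belonging)
  expect_identical(dict$entries$social_capital$parent, "belonging")
  expect_true(is.na(dict$entries$belonging$parent))
  # topics listed under an indicator are exactly those the mapping declares
  sc_topics <- vapply(dict$entries$social_capital$topics, `[[`, integer(1),
                      "topic_id")
  expect_identical(sc_topics, 1L)
  bel_topics <- vapply(dict$entries$belonging$topics, `[[`, integer(1),
                       "topic_id")
  expect_identical(bel_topics, c(1L, 2L))
  # indicator with no mapped topics gets an empty entry
  expect_length(dict$entries$learning$topics, 0)
  # per-topic content: label, weight share, ranked words, synonyms
  t1 <- dict$entries$belonging$topics[[1]]
  expect_identical(t1$label, "Gratitude")
  expect_identical(t1$top_words, c("a", "b", "c"))
  expect_equal(t1$weight_pct, unname(w["1"]))
  expect_length(t1$synonyms[["a"]], 2)
  expect_false("a" %in% t1$synonyms[["a"]])
})

test_that("dictionary exports write JSON, CSV, and Markdown", {
  Hp <- rbind(c(a = .6, b = .4))
  ens <- structure(list(Wp = diag(1), Hp = Hp, k_prime = 1L),
                   class = "ensemble_topic_model")
  D <- matrix(1, 2, 1, dimnames = list(c("p1", "p2"), NULL))
  map <- topic_indicator_map(list("1" = "learning"))
  ann <- annotate(D, map, rep("2018-Q3", 2))
  tax <- suppressMessages(infer_taxonomy(collect_post_sets(ann)))
  dict <- suppressMessages(assemble_dictionary(tax, map, topic_weights(D), ens))

  j <- tempfile(fileext = ".json"); write_dictionary_json(dict, j)
  parsed <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_equal(parsed$entries$learning$topics[[1]]$weight_pct, 100)

  csv <- tempfile(fileext = ".csv"); write_dictionary_csv(dict, csv)
  tab <- utils::read.csv(csv)
  expect_true("learning" %in% tab$indicator)

  md <- tempfile(fileext = ".md"); write_dictionary_md(dict, md)
  expect_true(any(grepl("learning", readLines(md))))
})

test_that("dictionary assembly is reproducible bit for bit", {
  corp <- generate_corpus(synthetic_config(windows = 2, docs_per_window = 120,
                                           seed = 3))
  corpus <- preprocess_corpus(corp$posts)
  vocab <- build_vocabulary(corpus)
  mats <- build_window_matrices(corpus, vocab)
  run_once <- function() {
    model <- fit_two_layer(mats, k = 5, k_prime = 5, seed = 2)
    emb <- train_embedding(corpus, dim = 16, epochs = 1, min_count = 2, seed = 2)
    map <- topic_indicator_map(stats::setNames(
      rep(list("learning"), 5), as.character(1:5)))
    ann <- suppressMessages(annotate(model$D, map, corpus))
    tax <- suppressMessages(infer_taxonomy(collect_post_sets(ann)))
    suppressMessages(assemble_dictionary(tax, map, topic_weights(model$D),
                                         model$ensemble, emb))
  }
  d1 <- run_once()
  d2 <- run_once()
  d1$metadata <- d2$metadata <- NULL
  expect_identical(d1, d2)
})
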