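test_that("deidentification blanks author ids and replaces mentions", {
  # identity case: no identifier anywhere
  p <- list(post_id = "p1", author_id = NA_character_,
            timestamp = "2018-07-01", text = "hello world")
  expect_identical(deidentify(p)$text, "hello world")

  # direct substitution, with and without the @ prefix
  p <- list(post_id = "p2", author_id = "user123",
            timestamp = "2018-07-01", text = "thanks @user123")
  expect_identical(deidentify(p)$text, "thanks [USER]")
  p$text <- "user123 said hi"
  expect_identical(deidentify(p)$text, "[USER] said hi")
  expect_true(is.na(deidentify(p)$author_id))
})

test_that("exactly the posts containing their author's name are altered", {
  set.seed(101)
  n <- 50
  authors <- sprintf("member%02d", seq_len(n))
  mention <- seq_len(n) %in% sample.int(n, 10)
  texts <- ifelse(mention,
                  paste("see you soon", authors),
                  "see you soon friend")
  posts <- make_posts(texts, authors = authors)
  changed <- vapply(seq_len(n), function(i) {
    p <- deidentify(as.list(posts[i, ]))
    p$text != texts[i]
  }, logical(1))
  # string-search oracle: precisely the posts whose text contains the name
  expect_identical(changed, mention)
  expect_identical(sum(changed), 10L)
})

test_that("tokenization lowercases, drops stopwords, and lemmatizes in order", {
  cfg <- preprocess_config(stopwords = c("the", "are"))
  expect_identical(tokenize_text("The cats are sleeping", cfg),
                   c("cat", "sleep"))
  expect_identical(tokenize_text("", cfg), character(0))
  expect_identical(tokenize_text(NA_character_, cfg), character(0))

  # default stopwords never survive, whatever the text
  set.seed(7)
  words <- c("is", "are", "the", "cat", "dog", "sleep", "walks", "happy")
  for (i in 1:20) {
    txt <- paste(sample(words, 12, replace = TRUE), collapse = " ")
    out <- tokenize_text(txt, preprocess_config())
    expect_false(any(out %in% c("is", "are", "the")))
    expect_false(any(out %in% default_stopwords()))
  }
})

test_that("POS lexicon filtering keeps only allowed tags", {
  lex <- c(cat = "NOUN", sleep = "VERB", quickly = "ADV", the = "DET",
           beside = "ADP")
  cfg <- preprocess_config(stopwords = character(0), pos_lexicon = lex)
  out <- tokenize_text("the cat sleeps quickly beside", cfg)
  expect_identical(out, c("cat", "sleep", "quickly"))
  # unknown tokens are kept
  expect_true("zzz" %in% tokenize_text("zzz cat", cfg))
})

test_that("length filtering keeps exactly the posts at or above threshold", {
  tc <- make_tokenized(list(letters[1:4], letters[1:5], letters[1:6],
                            character(0)))
  kept <- filter_short(tc, 5L)
  expect_identical(kept$post_id, c("p002", "p003"))

  # planted mix of 30 short among 100
  set.seed(11)
  lens <- c(rep(3, 30), rep(8, 70))[sample.int(100)]
  tc <- make_tokenized(lapply(lens, function(l) rep("w", l)))
  kept <- filter_short(tc, 5L)
  expect_identical(nrow(kept), 70L)
  expect_true(all(lengths(kept$terms) >= 5L))
  # idempotence
  expect_identical(filter_short(kept, 5L), kept)
})

test_that("calendar-quarter windows follow the month rule", {
  expect_identical(assign_window("2018-07-01"), "2018-Q3")
  expect_identical(assign_window("2018-09-30"), "2018-Q3")
  expect_identical(assign_window("2020-12-31"), "2020-Q4")
  expect_identical(assign_window("2019-01-01"), "2019-Q1")
  expect_identical(assign_window("2019-04-15"), "2019-Q2")
  expect_error(assign_window(list(post_id = "bad1", timestamp = "not-a-date")),
               "bad1")
})

test_that("preprocessing partitions retained posts disjointly over windows", {
  set.seed(5)
  months <- sprintf("2018-%02d-10", sample(1:12, 40, replace = TRUE))
  posts <- make_posts(rep("alpha bravo charlie delta echo foxtrot", 40),
                      timestamps = months)
  corpus <- preprocess_corpus(posts)
  expect_identical(nrow(corpus), 40L)
  expect_true(all(lengths(corpus$terms) >= 5L))
  # every post in exactly one window, and the window matches its timestamp
  expect_identical(corpus$window_id,
                   vapply(months, assign_window, character(1), USE.NAMES = FALSE))
})

test_that("retention report reproduces the percentage arithmetic", {
  rep <- preprocess_report(200, 150)
  expect_identical(rep$n_removed, 50)
  expect_equal(rep$retained_pct, 75)
  expect_equal(rep$removed_pct, 25)
  expect_error(preprocess_report(10, 11))
})

test_that("corpus round-trips through CSV and JSONL readers", {
  posts <- make_posts(c("one two three", "four five six"),
                      timestamps = c("2018-07-01", "2018-10-01"),
                      authors = c("a1", "a2"))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(posts, csv, row.names = FALSE)
  expect_identical(read_corpus(csv)$text, posts$text)

  jsonl <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(2), function(i) {
    jsonlite::toJSON(as.list(posts[i, ]), auto_unbox = TRUE)
  }, character(1)), jsonl)
  expect_identical(read_corpus(jsonl)$post_id, posts$post_id)
})

test_that("the natural-language sample corpus preprocesses end to end", {
  path <- system.file("extdata", "sample_posts.csv", package = "resdict")
  posts <- read_corpus(path)
  expect_identical(nrow(posts), 20L)
  corpus <- preprocess_corpus(posts)
  rep <- attr(corpus, "report")
  # the two deliberately short posts are dropped
  expect_identical(rep$n_retained, 18L)
  expect_false(any(c("n05", "n16") %in% corpus$post_id))
  # quarters span 2018-Q3 .. 2019-Q1
  expect_setequal(unique(corpus$window_id),
                  c("2018-Q3", "2018-Q4", "2019-Q1"))
  # stopwords are gone, mentions deidentified, lemmas grouped
  toks <- unlist(corpus$terms)
  expect_false(any(toks %in% c("the", "is", "are", "i", "my")))
  expect_false(any(grepl("riverbed", toks)))
  vocab <- build_vocabulary(corpus)
  expect_true(all(c("sleep", "friend", "help") %in% vocab))
})
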