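make_ann <- function(ind_sets, ids = NULL) {
  n <- length(ind_sets)
  out <- data.frame(
    post_id = if (is.null(ids)) sprintf("p%d", seq_len(n)) else ids,
    window_id = "2018-Q3", dominant_topic = 1L, dominant_weight = 1,
    stringsAsFactors = FALSE)
  out$indicators <- ind_sets
  class(out) <- c("annotated_posts", "data.frame")
  out
}

test_that("post sets invert the annotation table", {
  ann <- make_ann(list("belonging", c("belonging", "learning"), "learning"))
  sets <- collect_post_sets(ann, c("belonging", "learning", "self_efficacy"))
  expect_identical(sets$belonging, c("p1", "p2"))
  expect_identical(sets$learning, c("p2", "p3"))
  # never-assigned indicators still appear, empty
  expect_identical(sets$self_efficacy, character(0))
})

test_that("post sets equal a brute-force per-post scan", {
  set.seed(61)
  ind_sets <- lapply(1:500, function(i) {
    sample(RESILIENCE_INDICATORS, sample.int(3, 1))
  })
  ann <- make_ann(ind_sets)
  sets <- collect_post_sets(ann)
  for (ind in RESILIENCE_INDICATORS) {
    manual <- ann$post_id[vapply(ind_sets, function(s) ind %in% s, logical(1))]
    expect_identical(sets[[ind]], manual)
  }
})

test_that("strict subsumption finds proper-subset parents", {
  sets <- list(belonging = c("1", "2", "3"), social_capital = c("1", "2"),
               self_efficacy = "5")
  tax <- infer_taxonomy(sets)
  expect_identical(unname(tax$parent["social_capital"]), "belonging")
  expect_setequal(tax$roots, c("belonging", "self_efficacy"))

  # pairwise-disjoint sets give a flat forest
  sets <- list(belonging = c("1"), learning = c("2"), self_efficacy = c("3"))
  tax <- infer_taxonomy(sets)
  expect_setequal(tax$roots, names(sets))

  # nested chain resolves to the most specific subsumer
  sets <- list(belonging = as.character(1:6), social_capital = as.character(1:3),
               adaptive_capacity = as.character(1:2))
  tax <- infer_taxonomy(sets)
  expect_identical(unname(tax$parent["adaptive_capacity"]), "social_capital")
  expect_identical(unname(tax$parent["social_capital"]), "belonging")
})

test_that("equal post sets produce no edge", {
  sets <- list(belonging = c("1", "2"), learning = c("1", "2"))
  expect_message(tax <- infer_taxonomy(sets), "identical post sets")
  expect_setequal(tax$roots, c("belonging", "learning"))
})

test_that("strict-mode output is always a forest matching the subset oracle", {
  set.seed(71)
  for (trial in 1:60) {
    sets <- random_sets(n_ind = sample(3:5, 1), n_posts = sample(4:8, 1))
    if (all(lengths(sets) == 0L)) next
    tax <- suppressMessages(infer_taxonomy(sets))
    expect_identical(tax$parent, oracle_taxonomy(sets))
    # forest: walking up from any node terminates
    for (n in tax$nodes) {
      depth <- 0L; cur <- n
      while (!is.na(tax$parent[[cur]]) && depth <= length(tax$nodes)) {
        cur <- tax$parent[[cur]]; depth <- depth + 1L
      }
      expect_lte(depth, length(tax$nodes))
    }
  }
})

test_that("ancestor chains satisfy transitive containment", {
  set.seed(81)
  for (trial in 1:20) {
    sets <- random_sets(5, 10)
    if (all(lengths(sets) == 0L)) next
    tax <- suppressMessages(infer_taxonomy(sets))
    for (z in tax$nodes) {
      cur <- tax$parent[[z]]
      while (!is.na(cur)) {
        if (length(sets[[z]]) > 0L) {
          cont <- length(intersect(sets[[cur]], sets[[z]])) / length(sets[[z]])
          expect_gte(cont, tax$threshold)
        }
        cur <- tax$parent[[cur]]
      }
    }
  }
})

test_that("thresholded mode tolerates near-subsets", {
  sets <- list(belonging = as.character(1:10),
               social_capital = as.character(c(1:4, 99)))  # 80% contained
  strict <- infer_taxonomy(sets, mode = "strict")
  expect_true(is.na(strict$parent[["social_capital"]]))
  soft <- infer_taxonomy(sets, mode = "thresholded", threshold = 0.8)
  expect_identical(unname(soft$parent["social_capital"]), "belonging")
})

test_that("coverage is the set size over the union", {
  sets <- list(belonging = c("1", "2"), learning = c("2", "3"))
  cov <- coverage(sets)
  expect_equal(unname(cov), c(2 / 3, 2 / 3))
  expect_equal(unname(coverage(list(belonging = c("1", "2")))), 1)
  expect_error(coverage(list(a = character(0))), "empty union")

  set.seed(91)
  sets <- random_sets(5, 30)
  u <- length(unique(unlist(sets)))
  expect_equal(unname(coverage(sets)),
               unname(lengths(sets)) / u)
})

test_that("taxonomy exports to JSON and DOT", {
  sets <- list(belonging = c("1", "2", "3"), social_capital = c("1", "2"))
  tax <- infer_taxonomy(sets)
  j <- tempfile(fileext = ".json")
  write_taxonomy_json(tax, j)
  parsed <- jsonlite::fromJSON(j)
  expect_identical(parsed$parent$social_capital, "belonging")
  d <- tempfile(fileext = ".dot")
  write_taxonomy_dot(tax, d)
  expect_true(any(grepl("belonging\" -> \"social_capital", readLines(d))))
})
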