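# toy per-window matrices with well-separated term blocks
make_toy_windows <- function(Q = 2, docs = 12, terms_per_block = 4, k = 2,
                             seed = 1) {
  set.seed(seed)
  vocab <- sprintf("w%02d", seq_len(Q * k * terms_per_block))
  tc_list <- lapply(seq_len(Q), function(q) {
    docs_terms <- lapply(seq_len(docs), function(d) {
      block <- (q - 1) * k + sample.int(k, 1)
      pool <- vocab[(block - 1) * terms_per_block + seq_len(terms_per_block)]
      sample(pool, 8, replace = TRUE)
    })
    make_tokenized(docs_terms, windows = rep(sprintf("2018-Q%d", q), docs),
                   ids = sprintf("q%dp%03d", q, seq_len(docs)))
  })
  tc <- do.call(rbind, tc_list)
  class(tc) <- c("tokenized_corpus", "data.frame")
  vocab_all <- build_vocabulary(tc)
  list(corpus = tc, mats = build_window_matrices(tc, vocab_all))
}

test_that("base layer fits one model per window with shared k", {
  toy <- make_toy_windows(Q = 3, k = 2)
  base <- fit_base_layer(toy$mats, k = 2, seed = 1)
  expect_length(base, 3)
  expect_true(all(vapply(base, function(b) b$k, integer(1)) == 2L))
  for (b in base) {
    expect_equal(unname(rowSums(b$H)), rep(1, 2), tolerance = 1e-12)
  }
})

test_that("stacking produces Q*k rows with copy semantics and provenance", {
  toy <- make_toy_windows(Q = 2, k = 3)
  base <- fit_base_layer(toy$mats, k = 3, seed = 2)
  B <- stack_base_topics(base)
  expect_identical(nrow(B), 6L)
  origin <- attr(B, "row_origin")
  # row (q, j) of B equals row j of window q's H
  for (r in seq_len(nrow(B))) {
    q <- origin$window_id[r]
    j <- origin$topic[r]
    expect_equal(unname(B[r, ]), unname(base[[q]]$H[j, ]))
  }
})

test_that("ten windows at k = 10 stack into a 100-row base-topic matrix", {
  # shape contract of the stacked matrix: Q * k rows
  H_stub <- matrix(1 / 6, 10, 6, dimnames = list(NULL, sprintf("t%d", 1:6)))
  models <- lapply(1:10, function(q) {
    structure(list(window_id = sprintf("w%02d", q),
                   W = matrix(1, 2, 10,
                              dimnames = list(sprintf("q%dp%d", q, 1:2), NULL)),
                   H = H_stub, k = 10L),
              class = "base_topic_model")
  })
  B <- stack_base_topics(models)
  expect_identical(dim(B), c(100L, 6L))
})

test_that("ensemble recovers shared topics when every window agrees", {
  # all windows share identical H; k' = k must reproduce the shared topics
  set.seed(5)
  H_shared <- rbind(c(10, 8, 1, 0, 0, 0), c(0, 0, 1, 9, 7, 2))
  H_shared <- H_shared / rowSums(H_shared)
  colnames(H_shared) <- letters[1:6]
  B <- do.call(rbind, replicate(4, H_shared, simplify = FALSE))
  B <- B * (1 + 0.01 * matrix(runif(length(B)), nrow(B)))
  ens <- fit_ensemble(B, k_prime = 2, seed = 3)
  got <- vapply(1:2, function(t) paste(sort(top_terms(ens, t, 3)), collapse = " "),
                character(1))
  want <- vapply(1:2, function(t) {
    paste(sort(names(sort(H_shared[t, ], decreasing = TRUE))[1:3]), collapse = " ")
  }, character(1))
  expect_setequal(got, want)
  expect_equal(unname(rowSums(ens$Hp)), c(1, 1), tolerance = 1e-12)
})

test_that("rank-1 stacks factorize exactly at k' = 1", {
  h <- runif(8)
  B <- outer(c(1, 1, 1, 1), h / sum(h))
  colnames(B) <- sprintf("t%d", 1:8)
  ens <- fit_ensemble(B, k_prime = 1, seed = 1)
  expect_lt(ens$fit$error, 1e-6)
})

test_that("document block C is block-structured by window", {
  toy <- make_toy_windows(Q = 3, k = 2)
  base <- fit_base_layer(toy$mats, k = 2, seed = 4)
  C <- build_document_block(base)
  n2 <- nrow(base[[2]]$W)
  rows2 <- rownames(base[[2]]$W)
  # window-2 posts are zero outside columns 3-4
  expect_true(all(C[rows2, c(1, 2, 5, 6)] == 0))
  expect_equal(unname(C[rows2, 3:4]), unname(base[[2]]$W))
  # single window: C equals W
  one <- fit_base_layer(toy$mats[1], k = 2, seed = 4)
  expect_equal(unname(build_document_block(one)), unname(one[[1]]$W))
})

test_that("document block matches a hand-assembled toy and rejects duplicates", {
  mk <- function(win, ids, w) {
    structure(list(window_id = win,
                   W = matrix(w, 2, 1, dimnames = list(ids, NULL)),
                   H = matrix(1, 1, 3, dimnames = list(win, c("a", "b", "c"))),
                   k = 1L),
              class = "base_topic_model")
  }
  models <- list(mk("q1", c("p1", "p2"), c(0.2, 0.4)),
                 mk("q2", c("p3", "p4"), c(0.6, 0.8)))
  C <- build_document_block(models)
  expect_equal(unname(as.matrix(C)),
               rbind(c(0.2, 0), c(0.4, 0), c(0, 0.6), c(0, 0.8)))
  dup <- list(models[[1]], mk("q2", c("p1", "p4"), c(1, 1)))
  expect_error(build_document_block(dup), "more than one window")
})

test_that("document projection equals the matrix product and stays nonnegative", {
  C <- rbind(c(0.2, 0), c(0.4, 0), c(0, 0.6), c(0, 0.8))
  rownames(C) <- sprintf("p%d", 1:4)
  Wp <- rbind(c(0.7, 0.3), c(0.1, 0.9))
  ens <- structure(list(Wp = Wp, Hp = matrix(0.5, 2, 2), k_prime = 2L),
                   class = "ensemble_topic_model")
  D <- project_documents(C, ens)
  expect_equal(unname(D), C %*% Wp, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(D >= 0))
  # k' = 1: D proportional to C-weighted row mass
  ens1 <- structure(list(Wp = matrix(c(2, 3), 2, 1),
                         Hp = matrix(0.5, 1, 2), k_prime = 1L),
                    class = "ensemble_topic_model")
  expect_equal(unname(project_documents(C, ens1))[, 1],
               unname(C %*% c(2, 3))[, 1])
  expect_error(project_documents(C[, 1, drop = FALSE], ens), "mismatch")
})

test_that("top terms and posts rank by weight with stated tie-breaks", {
  Hp <- rbind(c(b = .3, a = .5, c = .2), c(b = .2, a = .2, c = .6))
  ens <- structure(list(Wp = diag(2), Hp = Hp, k_prime = 2L),
                   class = "ensemble_topic_model")
  expect_identical(top_terms(ens, 1, 3), c("a", "b", "c"))
  # sorting oracle on a random row
  set.seed(12)
  w <- runif(10); names(w) <- sprintf("t%02d", sample.int(10))
  ens2 <- structure(list(Wp = diag(1), Hp = matrix(w, 1, 10,
                                                   dimnames = list(NULL, names(w))),
                         k_prime = 1L), class = "ensemble_topic_model")
  expect_identical(top_terms(ens2, 1, 10), names(sort(-w)))
  # ties break lexicographically; N beyond vocabulary truncates
  expect_identical(top_terms(ens, 2, 99), c("c", "a", "b"))
  # one-hot row puts its term first
  expect_identical(top_terms(ens, 2, 1), "c")

  D <- cbind(c(.1, .5, .3), c(.4, .4, .2))
  rownames(D) <- c("p1", "p2", "p3")
  expect_identical(top_posts(D, 1, 2), c("p2", "p3"))
  # ties by post order; M beyond corpus truncates
  expect_identical(top_posts(D, 2, 99), c("p1", "p2", "p3"))
  expect_identical(top_posts(D[1, , drop = FALSE], 1, 5), "p1")
})

test_that("column-mismatched base models refuse to stack", {
  mk <- function(m) structure(list(window_id = "q", W = matrix(1, 1, 1),
                                   H = matrix(1, 1, m), k = 1L),
                              class = "base_topic_model")
  expect_error(stack_base_topics(list(mk(3), mk(4))), "disagree")
})
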