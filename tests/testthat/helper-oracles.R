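# Independent oracles used across the suite. Each is written from the
# definition it checks, not from the implementation under test.

# plain-loop multiplicative-update NMF: fixed iteration budget, explicit
# elementwise loops over the update formulas
oracle_nmf_mu <- function(A, W, H, iters) {
  A <- as.matrix(A)
  eps <- 1e-10
  for (it in seq_len(iters)) {
    WtA <- t(W) %*% A
    WtWH <- t(W) %*% W %*% H
    for (i in seq_len(nrow(H))) for (j in seq_len(ncol(H))) {
      H[i, j] <- H[i, j] * WtA[i, j] / (WtWH[i, j] + eps)
    }
    AHt <- A %*% t(H)
    WHHt <- W %*% H %*% t(H)
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      W[i, j] <- W[i, j] * AHt[i, j] / (WHHt[i, j] + eps)
    }
  }
  list(W = W, H = H, error = sqrt(sum((A - W %*% H)^2)))
}

# brute-force subsumption: checks every ordered pair directly against the
# containment definition, then picks the smallest qualifying parent
oracle_taxonomy <- function(sets, t = 1) {
  nodes <- names(sets)
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (y in nodes) {
    if (length(sets[[y]]) == 0L) next
    best <- NA_character_
    best_size <- Inf
    for (x in nodes) {
      if (x == y || length(sets[[x]]) == 0L) next
      fwd <- length(intersect(sets[[x]], sets[[y]])) / length(sets[[y]])
      rev <- length(intersect(sets[[x]], sets[[y]])) / length(sets[[x]])
      if (fwd >= t && rev < fwd) {
        if (length(sets[[x]]) < best_size ||
            (length(sets[[x]]) == best_size && x < best)) {
          best <- x
          best_size <- length(sets[[x]])
        }
      }
    }
    parent[y] <- best
  }
  parent
}

# linear-scan argmax with lowest-index tie-break and all-zero sentinel
oracle_argmax <- function(row) {
  best <- -Inf
  idx <- NA_integer_
  for (j in seq_along(row)) {
    if (row[j] > best) {
      best <- row[j]
      idx <- j
    }
  }
  if (best <= 0) NA_integer_ else idx
}

# brute-force TF-IDF with the stated formula (raw tf, smoothed idf within
# the window, L2 row normalization)
oracle_tfidf <- function(docs, vocab) {
  n <- length(docs)
  M <- matrix(0, n, length(vocab), dimnames = list(names(docs), vocab))
  df <- sapply(vocab, function(t) sum(sapply(docs, function(d) t %in% d)))
  idf <- log((1 + n) / (1 + df)) + 1
  for (i in seq_len(n)) {
    for (t in vocab) {
      M[i, t] <- sum(docs[[i]] == t) * idf[[t]]
    }
    nrm <- sqrt(sum(M[i, ]^2))
    if (nrm > 0) M[i, ] <- M[i, ] / nrm
  }
  M
}

# small raw-post data.frame builder
make_posts <- function(texts, timestamps = NULL, authors = NULL) {
  n <- length(texts)
  data.frame(
    post_id = sprintf("p%03d", seq_len(n)),
    author_id = if (is.null(authors)) NA_character_ else authors,
    timestamp = if (is.null(timestamps)) rep("2018-07-15", n) else timestamps,
    text = texts,
    stringsAsFactors = FALSE)
}

# tokenized corpus built directly from term lists (bypasses the linguistic
# path; used when a test needs exact control over terms)
make_tokenized <- function(terms, windows = NULL, ids = NULL) {
  n <- length(terms)
  out <- data.frame(
    post_id = if (is.null(ids)) sprintf("p%03d", seq_len(n)) else ids,
    window_id = if (is.null(windows)) rep("2018-Q3", n) else windows,
    stringsAsFactors = FALSE)
  out$terms <- terms
  class(out) <- c("tokenized_corpus", "data.frame")
  out
}

# synthetic stacked matrix with exactly `n_prof` distinct topic profiles
# plus noise, and a cluster word embedding aligned with the profiles
make_planted_B <- function(seed, n_prof = 5, supp = 15, m = 100, rows = 20,
                           noise = 0.1, emb_dim = 20, jitter = 0.3) {
  set.seed(seed)
  profiles <- matrix(0, n_prof, m)
  for (p in seq_len(n_prof)) {
    w <- 0.8^(0:(supp - 1))
    profiles[p, (p - 1) * supp + seq_len(supp)] <- w / sum(w)
  }
  B <- matrix(0, rows, m)
  for (r in seq_len(rows)) {
    p <- ((r - 1) %% n_prof) + 1
    nz <- stats::runif(m)
    B[r, ] <- (1 - noise) * profiles[p, ] + noise * nz / sum(nz)
  }
  colnames(B) <- sprintf("term%03d", seq_len(m))
  V <- matrix(stats::rnorm(m * emb_dim), m, emb_dim)
  for (p in seq_len(n_prof)) {
    ctr <- stats::rnorm(emb_dim)
    idx <- (p - 1) * supp + seq_len(supp)
    V[idx, ] <- matrix(ctr, supp, emb_dim, byrow = TRUE) +
      jitter * matrix(stats::rnorm(supp * emb_dim), supp, emb_dim)
  }
  rownames(V) <- colnames(B)
  list(B = B, embedding = word_embedding(V))
}

# random indicator post-set configuration over a small post universe
random_sets <- function(n_ind, n_posts) {
  posts <- sprintf("p%d", seq_len(n_posts))
  sets <- lapply(seq_len(n_ind), function(i) {
    posts[stats::runif(n_posts) < 0.5]
  })
  stats::setNames(sets, RESILIENCE_INDICATORS[seq_len(n_ind)])
}
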