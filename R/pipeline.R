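# End-to-end orchestration of the four phases from one configuration.
# The topic-to-indicator mapping is a human step: when the config names no
# mapping file the run halts after topic fitting and writes a mapping
# template (top terms and top posts per topic) for the qualitative coding.

#' Pipeline configuration
#'
#' Defaults are the study settings: base topic count `k = 10`, candidate
#' ensemble range `k' = 10..20` selected by coherence, 15 terms / 20 posts
#' in the mapping template, coherence over the top 10 terms, strict
#' subsumption, and skip-gram embedding defaults.
#'
#' @param input Path to the raw corpus (CSV or JSONL), or a raw-post
#'   data.frame.
#' @param output_dir Artifact directory.
#' @param topic_map Optional path to the topic-to-indicator mapping (YAML or
#'   JSON) or a `topic_indicator_map`; absent, the run stops after fitting
#'   with a mapping template.
#' @param k Base topic count per window.
#' @param k_prime Fixed ensemble topic count; `NULL` selects from
#'   `k_prime_range` by coherence.
#' @param k_prime_range Candidate ensemble counts.
#' @param n_map Terms per topic in the mapping template (default 15).
#' @param n_coherence Terms per topic for coherence (default 10).
#' @param m_posts Posts per topic in the mapping template (default 20).
#' @param preprocess A [preprocess_config()].
#' @param embedding_params List of [train_embedding()] arguments.
#' @param subsumption_mode `"strict"` or `"thresholded"`.
#' @param subsumption_threshold Containment threshold for thresholded mode.
#' @param seed Master seed for every random stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, topic_map = NULL,
                            k = 10L, k_prime = NULL, k_prime_range = 10:20,
                            n_map = 15L, n_coherence = 10L, m_posts = 20L,
                            preprocess = preprocess_config(),
                            embedding_params = list(),
                            subsumption_mode = "strict",
                            subsumption_threshold = 0.8,
                            seed = 1L) {
  structure(list(input = input, output_dir = output_dir,
                 topic_map = topic_map, k = as.integer(k),
                 k_prime = if (is.null(k_prime)) NULL else as.integer(k_prime),
                 k_prime_range = as.integer(k_prime_range),
                 n_map = as.integer(n_map),
                 n_coherence = as.integer(n_coherence),
                 m_posts = as.integer(m_posts),
                 preprocess = preprocess,
                 embedding_params = embedding_params,
                 subsumption_mode = subsumption_mode,
                 subsumption_threshold = subsumption_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Phases: (1) preprocessing and quarter windowing; (2) TF-IDF, two-layer
#' NMF with embedding training and coherence-based selection of `k'`;
#' (3) annotation and prevalence (requires the human mapping); (4) taxonomy
#' and dictionary. All artifacts (reports, MTX matrices, CSV tables, JSON
#' exports, run manifest) are written under `config$output_dir`; without a
#' mapping the run stops after phase 2 and writes `mapping_template.csv`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory artifacts (`corpus`, `model`,
#'   `coherence`, `embedding`, and when mapped: `annotated`, `prevalence`,
#'   `taxonomy`, `dictionary`).
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # Phase 1 ----------------------------------------------------------------
  posts <- if (is.data.frame(config$input)) config$input else read_corpus(config$input)
  corpus <- preprocess_corpus(posts, config$preprocess)
  report <- attr(corpus, "report")
  message(sprintf("phase 1: %d/%d posts retained (%.2f%%)",
                  report$n_retained, report$n_input, report$retained_pct))
  jsonlite::write_json(report, file.path(out, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tokenized(corpus, file.path(out, "tokenized.jsonl"))

  # Phase 2 ----------------------------------------------------------------
  vocab <- build_vocabulary(corpus)
  writeLines(vocab, file.path(out, "vocabulary.txt"))
  mats <- build_window_matrices(corpus, vocab)
  message(sprintf("phase 2: %d windows, %d terms", length(mats), length(vocab)))

  emb_args <- c(list(corpus = corpus, seed = seed), config$embedding_params)
  embedding <- do.call(train_embedding, emb_args)
  write_embedding(embedding, file.path(out, "embedding.txt"))

  base <- fit_base_layer(mats, k = config$k, seed = seed)
  B <- stack_base_topics(base)
  coh <- NULL
  if (is.null(config$k_prime)) {
    coh <- select_k_prime(B, config$k_prime_range, embedding,
                          n_terms = config$n_coherence, seed = seed)
    utils::write.csv(coh$report, file.path(out, "coherence.csv"),
                     row.names = FALSE)
    k_prime <- coh$chosen
    message("phase 2: coherence selected k' = ", k_prime)
  } else {
    k_prime <- config$k_prime
  }
  ensemble <- fit_ensemble(B, k_prime = k_prime, seed = seed + length(base))
  C <- build_document_block(base)
  D <- project_documents(C, ensemble)
  model <- list(base = base, B = B, ensemble = ensemble, C = C, D = D)
  .write_model_bundle(model, vocab, file.path(out, "model"))

  manifest <- list(seed = seed, k = config$k, k_prime = k_prime,
                   k_prime_range = config$k_prime_range,
                   n_map = config$n_map, n_coherence = config$n_coherence,
                   m_posts = config$m_posts,
                   windows = names(mats), n_posts = nrow(corpus),
                   n_terms = length(vocab),
                   subsumption = list(mode = config$subsumption_mode,
                                      threshold = config$subsumption_threshold),
                   embedding = embedding$params)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  # Human break point -------------------------------------------------------
  map <- config$topic_map
  if (is.null(map)) {
    tmpl <- mapping_template(model, config$n_map, config$m_posts)
    utils::write.csv(tmpl, file.path(out, "mapping_template.csv"),
                     row.names = FALSE)
    message("no topic map supplied; wrote mapping_template.csv and stopped after phase 2")
    return(invisible(list(corpus = corpus, model = model, coherence = coh,
                          embedding = embedding, template = tmpl)))
  }
  if (is.character(map)) map <- read_topic_map(map)

  # Phase 3 ----------------------------------------------------------------
  ann <- annotate(D, map, corpus)
  utils::write.csv(flatten_annotations(ann), file.path(out, "annotations.csv"),
                   row.names = FALSE)
  prev <- prevalence(ann)
  utils::write.csv(prev, file.path(out, "prevalence.csv"), row.names = FALSE)

  # Phase 4 ----------------------------------------------------------------
  sets <- collect_post_sets(ann)
  tax <- infer_taxonomy(sets, mode = config$subsumption_mode,
                        threshold = config$subsumption_threshold)
  write_taxonomy_json(tax, file.path(out, "taxonomy.json"))
  write_taxonomy_dot(tax, file.path(out, "taxonomy.dot"))
  cov <- coverage(sets)
  utils::write.csv(data.frame(indicator = names(cov), coverage = unname(cov)),
                   file.path(out, "coverage.csv"), row.names = FALSE)

  weights <- topic_weights(D)
  dict <- assemble_dictionary(tax, map, weights, ensemble, embedding,
                              metadata = list(seed = seed, k = config$k,
                                              k_prime = k_prime))
  write_dictionary_json(dict, file.path(out, "dictionary.json"))
  write_dictionary_csv(dict, file.path(out, "dictionary.csv"))
  write_dictionary_md(dict, file.path(out, "dictionary.md"))
  message("pipeline complete: artifacts in ", out)

  invisible(list(corpus = corpus, model = model, coherence = coh,
                 embedding = embedding, annotated = ann, prevalence = prev,
                 taxonomy = tax, dictionary = dict))
}

#' Mapping template for the qualitative coding step
#'
#' One row per ensemble topic with its top terms and most relevant posts;
#' the human coding fills in the indicator column and the result is read
#' back with [read_topic_map()].
#'
#' @param model Output of [fit_two_layer()] (or the model part of a
#'   pipeline run).
#' @param n_terms Terms per topic (default 15).
#' @param m_posts Posts per topic (default 20).
#' @return data.frame: `topic`, `top_terms`, `top_posts`, empty
#'   `indicators`.
#' @export
mapping_template <- function(model, n_terms = 15L, m_posts = 20L) {
  ens <- model$ensemble
  data.frame(
    topic = seq_len(ens$k_prime),
    top_terms = vapply(seq_len(ens$k_prime), function(t)
      paste(top_terms(ens, t, n_terms), collapse = ";"), character(1)),
    top_posts = vapply(seq_len(ens$k_prime), function(t)
      paste(top_posts(model$D, t, m_posts), collapse = ";"), character(1)),
    indicators = "",
    stringsAsFactors = FALSE)
}

.write_model_bundle <- function(model, vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, name) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(M)),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(dir, paste0(name, ".mtx")))
  }
  for (b in model$base) {
    wm(b$W, paste0("W_", b$window_id))
    wm(b$H, paste0("H_", b$window_id))
  }
  wm(model$B, "B"); wm(model$ensemble$Wp, "Wprime")
  wm(model$ensemble$Hp, "Hprime"); wm(model$C, "C"); wm(model$D, "D")
  writeLines(vocab, file.path(dir, "vocabulary.txt"))
  jsonlite::write_json(
    list(post_ids = rownames(model$D),
         row_origin = model$ensemble$row_origin,
         k = model$base[[1]]$k, k_prime = model$ensemble$k_prime),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
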