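# resdict

Peer-support mental-health forums leave a long written trace of how their
members cope, connect, and recover. `resdict` turns such a trace — a
time-stamped corpus of forum posts — into a **resilience dictionary**: a
machine-readable vocabulary that describes how five strengths-based
resilience indicators (*social capital*, *belonging*, *learning*, *adaptive
capacity*, *self-efficacy*) are realized in the community's own language,
how prevalent each indicator is over time, and how the indicators nest
inside one another.

The package is aimed at digital-health and computational-social-science
researchers who have forum data, want topic-level structure they can
qualitatively audit, and need every step to be reproducible from a seed.

## The method

The pipeline has four phases; the third contains a deliberate human step.

1. **Preprocessing.** Posts are deidentified (author identifiers blanked
   and in-text mentions replaced by `[USER]`), sentence-split, tokenized,
   stopword-filtered, lemmatized, and pruned when shorter than 5 terms.
   Each retained post is assigned to a calendar quarter.
2. **Two-layered NMF topic modeling.** For each quarter, a TF-IDF
   document-term matrix A (posts × terms over a global vocabulary) is
   factorized as A ≈ W H with k nonnegative base topics. The per-quarter
   topic-term matrices H are stacked row-wise into B ((Q·k) × m), and a
   second factorization B ≈ W′ H′ yields k′ *ensemble topics* that persist
   across quarters. Stacking the per-quarter W into a block matrix C and
   projecting, D = C W′, gives every post a membership weight on every
   ensemble topic. Each row of H′ is normalized so a topic's term weights
   sum to 1. The ensemble size k′ is chosen by *topic coherence*: the mean
   pairwise cosine similarity of each topic's top-10 terms in a skip-gram
   word-embedding space trained on the full corpus.
3. **Annotation.** A reviewed topic → indicator mapping (the qualitative
   coding output; the package emits a template of top-15 terms and top-20
   posts per topic to support it) annotates each post with the indicators
   of its dominant topic, and per-quarter indicator prevalence is the
   proportion of the quarter's posts so annotated.
4. **Taxonomy and dictionary.** Indicator x *subsumes* y when the posts
   annotated with y are a (proper) subset of those annotated with x;
   the resulting forest, plus per-topic weight shares, top-10 topic words,
   and 5 embedding neighbors per word, is assembled into the dictionary
   (JSON / CSV / Markdown).

Because real forum corpora are typically private, the package ships a
synthetic-corpus generator with complete ground truth (planted topics,
indicator nesting, prevalences, synonym pairs) so the whole pipeline is
testable end to end.

## Worked example

```r
library(resdict)

corp   <- generate_corpus(synthetic_config(windows = 2, docs_per_window = 250,
                                           seed = 42))
corpus <- preprocess_corpus(corp$posts)
corpus
#> Tokenized corpus: 449 posts, 2 windows (2018-Q3, 2018-Q4), 14070 term tokens

vocab <- build_vocabulary(corpus)
mats  <- build_window_matrices(corpus, vocab)
model <- fit_two_layer(mats, k = 5, k_prime = 7, seed = 1)
model$ensemble
#> Ensemble topic model: k' = 7 topics over 10 base topics, 292 terms

emb <- train_embedding(corpus, dim = 50, epochs = 3, min_count = 3, seed = 1)
rec <- evaluate_recovery(model, corpus, corp$truth, emb)
round(rec$mean_topic_overlap, 3)   # 0.9  : top-10 terms of planted topics recovered
round(rec$max_prevalence_error, 4) # 0.0044 : worst per-quarter prevalence error
rec$taxonomy
#> Resilience taxonomy (strict mode)
#> - belonging
#>   - social_capital
#> - learning
#>   - adaptive_capacity
#> - self_efficacy

round(topic_weights(model$D), 1)
#>    1    2    3    4    5    6    7
#> 21.2 21.5 17.4 10.4  9.9 10.9  8.7
```

The recovery report says that, on this 500-post toy corpus, fitted ensemble
topics reproduce 90% of the planted topics' top-10 terms, per-quarter
indicator prevalences are recovered to a fraction of a percentage point,
and strict subsumption over the annotations reproduces the planted nesting
exactly (social capital under belonging, adaptive capacity under learning,
self-efficacy independent). Topic weights are each topic's share of
dominant-post mass and sum to 100.

On real data you would replace `generate_corpus()` with
`read_corpus("posts.csv")`, run `run_pipeline()` without a mapping to get
`mapping_template.csv`, code the topics, and rerun with the completed
mapping; `inst/cli/resdict` wraps the same stages as a command-line tool.

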