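---
title: "Mining resilience indicators from forum text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining resilience indicators from forum text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`resdict` builds a resilience dictionary from a time-stamped corpus of
peer-support forum posts. This vignette is the package's account of the
method: the model, its assumptions, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The model

### Windowed corpora and TF-IDF

Posts are partitioned into calendar quarters — long enough for stable topic
estimates, short enough that seasonal themes (holidays, anniversaries)
stay visible. Each quarter's retained posts become a nonnegative
document-term matrix over one *global* vocabulary (the sorted union of all
terms): keeping columns aligned across quarters is what later allows
topic-term matrices from different quarters to be stacked.

Weights are raw term frequency times a smoothed inverse document frequency,
$\mathrm{idf}(t) = \ln\frac{1+n}{1+\mathrm{df}(t)} + 1$, with $n$ and
$\mathrm{df}$ computed *within* the quarter (each quarter is modeled as its
own collection, so a term's rarity is judged against its contemporaries),
and rows are L2-normalized so long posts do not dominate the factorization.
Raw-vs-log tf, the idf smoothing, and row normalization are conventions,
not theory; they are fixed here and exposed nowhere precisely because
switching them silently changes every downstream weight.

### Two-layered NMF

Within each quarter $q$, NMF factorizes $A_q \approx W_q H_q$ into $k$
*base topics*. The $H_q$ are stacked into $B$ ($(Q \cdot k) \times m$), and a
second NMF $B \approx W' H'$ yields $k'$ *ensemble topics*: recurring
base-topic profiles across the timeline. A base topic that appears in every
quarter collapses into one ensemble topic; a quarter-specific theme
survives as its own.

Before stacking, every row of each $H_q$ is normalized to unit sum (with
the inverse scale folded into $W_q$, leaving the product unchanged). Two
reasons: quarters differ in size and scale, and without per-topic
normalization a large quarter would dominate $B$; and the convention that a
topic's term weights sum to 1 makes term weights interpretable as shares
and is asserted throughout the package.

Posts are carried to the ensemble level by stacking the $W_q$ into a block
matrix $C$ ($n \times Q k$): a post's row holds its quarter's membership
weights in that quarter's $k$ columns and zeros elsewhere, since a post
exists in exactly one quarter. The document-ensemble matrix is the
projection

$$D = C \, W',$$

the unique dimensionally consistent product that gives one row per original
post and one column per ensemble topic; entry $(i, j)$ aggregates post
$i$'s base-topic memberships weighted by how much each base topic belongs
to ensemble topic $j$. $D$ is nonnegative by construction.

### Choosing the number of ensemble topics

There is no universal rule for $k'$. The package scores each candidate by
*topic coherence*: the mean pairwise cosine similarity of a topic's top-10
terms in a word-embedding space trained on the full retained corpus, then
averaged over the candidate model's topics; the maximizer wins, smaller
$k'$ on ties. The intuition: when $k'$ is too small, unrelated profiles
merge and a topic's top terms scatter across embedding clusters; when too
large, surplus topics fit noise whose top terms are incoherent. Mean
pairwise cosine (rather than, say, a median) is used because it is the
simplest aggregation that penalizes every incoherent pair; terms missing
from the embedding vocabulary are skipped and recorded, and a topic with
fewer than two embeddable terms scores 0 with a warning rather than
failing the run.

### Annotation, prevalence, taxonomy, dictionary

The mapping from topics to the five resilience indicators is a human,
qualitative step. The package consumes it as a reviewed configuration file
and deliberately does not automate it; without one, a pipeline run halts
after topic fitting and emits a template with each topic's top-15 terms and
top-20 posts — the evidence the coding is based on.

Each post is annotated with its *dominant* topic (row argmax of $D$; ties
broken by lowest index and logged; all-zero rows get a "no topic" sentinel)
and inherits that topic's indicator set. Prevalence of an indicator in a
quarter is the fraction of the quarter's retained posts so annotated. The
denominator includes posts with unmapped dominant topics, keeping quarters
comparable; because a topic can map to several indicators, prevalences may
sum above 1 within a quarter, and that is asserted rather than
"corrected".

The taxonomy uses subsumption over annotation co-occurrence: indicator $x$
subsumes $y$ when $y$'s posts are contained in $x$'s. Strict mode (the
default) demands proper containment, under which the subset relation is a
partial order and the output is always a forest. Real annotations rarely
satisfy exact subsets, so a thresholded mode accepts containment fractions
$\geq t$ (default 0.8 when enabled, after the classical subsumption
literature) and additionally requires the forward containment to exceed
the reverse one, which rules out equal sets (logged, no edge). When several
subsumers qualify, the *most specific* (smallest post set) becomes the
parent, yielding the deepest valid hierarchy. Thresholded containment is
not antisymmetric in pathological configurations, so a cycle check errors
with the offending chain.

The dictionary assembles, per indicator: its taxonomy parent, its topics,
each topic's weight share, top-10 words, and 5 embedding neighbors per
word. A topic's weight is the sum of dominant weights over posts whose
dominant topic it is, normalized across topics to percentages — so weights
sum to 100 and read as relative importance. (The alternative reading, a
per-post average, does not produce a distribution and would make weights
incomparable across corpora of different sizes.)

### Word embeddings

The embedding is a skip-gram model with negative sampling, implemented in
compiled code, single-threaded with its own RNG so training is
bit-reproducible given the seed. Defaults: 100 dimensions, context window
5, minimum count 5, 5 epochs, 5 negative samples, initial learning rate
0.025 with linear decay — the de-facto standard settings for this model
family on midsized corpora. Embedding neighbors are distributional, not
lexicographic: antonym-style neighbors can and do appear, and the package
does not filter them.

## Preprocessing choices

* **Stopwords** default to a standard English function-word list;
  overridable.
* **Lemmatization** is rule-based (an irregular-form table plus plural /
  `-ing` / `-ed` suffix rules). It is deterministic, dependency-free, and
  deliberately conservative; it will miss irregular forms outside its
  table and occasionally truncate (e.g. *making → mak*). For term-counting
  purposes this is an acceptable trade; a caller needing exact lemmas can
  pre-lemmatize and feed pseudo-tokens through unchanged (tokens containing
  digits are never rewritten).
* **Part-of-speech filtering** is lexicon-driven: supply a term → tag
  lexicon and only the allowed tags (default: nouns, verbs, adjectives,
  adverbs) survive; unknown tokens pass. Without a lexicon, no POS filter
  is applied and stopword removal alone strips the closed-class words. This
  keeps the linguistic dependencies of the package at zero while leaving
  the content-word filter available where a tagger's output exists.
* **Length filter**: posts with fewer than 5 terms are removed — too short
  to carry topical signal. The rule is strictly "count < threshold", with
  the threshold in configuration.

## Numerical choices

* **NMF solver**: multiplicative updates under Frobenius loss, 500
  iteration cap, relative-improvement tolerance $10^{-6}$ checked every 10
  iterations, with a $10^{-10}$ guard in denominators. Multiplicative
  updates never increase the error; the fit records its error trace and
  the suite asserts monotone descent.
* **Initialization**: nonnegative double SVD, with structural zeros filled
  by small seeded random values (the "ar" variant). NNDSVD makes runs
  largely deterministic and fast to converge; the random fill avoids the
  zero-locking of multiplicative updates and is the only seed-sensitive
  part of a fit.
* **Tie-breaks** are deterministic everywhere: term ranking breaks ties
  lexicographically, post ranking by corpus order, argmax by lowest index,
  parent selection by smallest set then name. Reruns with the same seed
  are bit-identical, which the suite also asserts.
* **Degenerate inputs** error early and by name: empty corpora, empty
  windows, rank-exceeding $k$, non-finite matrix entries, misaligned
  dimensions.

## The synthetic corpus and what it shows

The generator emulates the structure the pipeline is built for, with
complete bookkeeping: $Q$ quarters (default 4, from 2018-Q3) of 500 posts
each; per quarter, 3 topics shared across the whole timeline and 2
quarter-specific ones (so a matched base-topic count of 5); disjoint
30-term topic supports with geometrically decaying weights plus a 50-term
uniform background absorbing 10% of token draws; document lengths
Poisson-distributed around 30 terms with 10% of posts forced under the
length filter; a dominant-topic mixture weight of 0.75. Indicators follow a
nested design — social-capital topics are also belonging topics,
adaptive-capacity topics also learning topics, self-efficacy topics carry
nothing else — so the true subsumption forest is known. Eight synonym
pairs are planted as interchangeable low-mass members of the shared
topics, each pair followed by its own two collocate terms; synonymy is
thereby encoded the way embeddings can see it (identical context
distributions plus a private collocational signature), and pairs sit on
persistent topics because skip-gram similarity is unreliable below a few
hundred occurrences. Pseudo-words (`w0123`) pass the linguistic stages
unchanged; the natural-language path is exercised separately by
hand-written fixtures in the tests.

Validation problem sizes: recovery is demonstrated at 2,000 posts per
quarter (mean top-10 term overlap ≥ 0.8, prevalence errors within 3
percentage points, exact taxonomy recovery), normalization and structural
contracts at ~2,000 posts total, and coherence-based selection on stacked
matrices with 5 planted profiles over candidates 2–8 across 10 seeds.

What passing these tests does *not* show: real forum language is not a
mixture of disjoint sparse supports — topics share vocabulary, drift
within a quarter, and correlate with authorship; real annotations are
noisy enough that strict subsumption rarely holds exactly (hence the
thresholded mode); and real synonymy is far messier than planted
collocational twins. The synthetic results certify the machinery —
factorization, projection, bookkeeping, inference rules — not the
linguistic fidelity of any particular corpus.

## Known limitations

* Deidentification replaces author identifiers only; free-text names of
  third parties are out of scope and need a dedicated NER pass upstream.
* The lemmatizer and stopword list are English-only.
* Strict subsumption on large real corpora will usually return a flat
  forest; use thresholded mode and report the containment fractions, which
  the taxonomy object retains.
* Coherence-based selection inherits the embedding's biases: very rare
  top terms fall below the embedding's minimum count and are skipped in
  scoring.
* The NMF layers are dense in memory; corpora beyond roughly $10^5$ posts
  per window deserve a sparse-aware solver.
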