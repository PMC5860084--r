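---
title: "Classifying sentences by the Hallmarks of Cancer and mining the result"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sentences by the Hallmarks of Cancer and mining the result}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Hallmarks of Cancer organize the behaviour of malignant cells into ten
canonical capabilities — sustaining proliferative signalling, resisting cell
death, inducing angiogenesis, and so on. A literature collection annotated
with these hallmarks can be queried semantically: *which hallmarks does the
literature associate with cisplatin? with EGF? do two drugs have different
hallmark profiles?* Answering such questions at scale requires (i) a
classifier that assigns hallmark labels to individual sentences and (ii) an
analytics layer that turns sentence-level co-occurrence between a free-text
query and the assigned labels into association statistics.

`hallmarker` implements both. The taxonomy is a two-level forest of 37
nodes: the ten hallmarks plus 27 cellular/molecular process subclasses,
identified by dotted codes (`"3"` resisting cell death, `"3.1"` apoptosis,
`"7.1.2"` DNA strand breaks). One published subclass listing assigns the
prefix `2.1` to two different subclasses of hallmark 2; because codes are
dictionary keys here, the second ("By evading contact inhibition") is stored
as `"2.2"` with its name unchanged.

## The classification model

Each taxonomy node gets an independent binary linear support vector machine
(one-vs-rest), so a sentence can receive any subset of the 37 labels.
Three design elements deal with the structure of the data:

* **Hypernym label propagation.** A sentence annotated `"3.1"` (apoptosis)
  is counted as a positive example of `"3"` (resisting cell death) when the
  parent's classifier is trained: training labels are the ancestor closure
  of the gold labels.
* **Inverse-proportional class weighting.** Positives are rare (roughly a
  quarter of sentences carry any label, and each node sees far fewer), so
  the hinge-loss cost of each class is scaled by `w_c = N / (2 n_c)`. Any
  global factor is absorbed by the cost parameter `C`.
* **Parent-favoring post-processing.** The 37 independent decisions can
  disagree with the hierarchy. A top-down pass suppresses any positive
  whose parent was resolved negative (the parent's classifiers see more
  data and are on average stronger); parent-positive/child-negative is not
  a disagreement because subclasses are not exhaustive. The result always
  satisfies "a node is labelled only if all its ancestors are", and the
  pass is idempotent. Multi-level chains are resolved top-down, so a
  negative mid-level node suppresses its whole subtree.

### Features

Seven binary feature families describe a sentence; each node's classifier
uses its own selected subset of them (sparse binary design matrix):

1. **LBOW** — lemmatized bag of words, stopwords removed.
2. **NGRAM** — token bigrams and trigrams (tokens, not lemmas; the choice
   is documented here because either reading is defensible).
3. **VC** — verb classes from a lexicon mapping verb lemmas to cluster ids,
   abstracting over individual predicates. The shipped lexicon is a small
   synthetic stand-in for an externally induced clustering of 399 verbs;
   any `lemma → class` TSV can be plugged in.
4. **NE** — named entities of the five types most relevant to cancer text
   (Protein, DNA, RNA, Cell_line, Cell_type). Both a bare-type key and a
   type:surface key are emitted; bare types alone carry almost no
   information. The default tagger is a gazetteer over shipped synthetic
   term lists; a production tagger plugs in through the
   `function(tokens) -> tags` contract.
5. **MESH** and 6. **CHEM** — MeSH descriptors and chemical-substance names
   attached to the *abstract* by PubMed, copied onto every sentence of the
   abstract.
7. **SD** — semantic distance: the maximum cosine similarity between the
   sentence's lemmas and the node's label vector in a jointly trained
   word–label embedding, discretized into `B = 10` equal-width bins over
   `[-1, 1]` and emitted as a single indicator key. Ten bins is the
   smallest resolution that separates "near the label" from "unrelated"
   without fragmenting the training signal; `B` is configurable.

**Feature selection** is per node: candidate keys must occur in at least
one sentence of an abstract annotated (after closure) with the node, and
their corpus-wide sentence document frequency must lie in
`[min_count, max_count]` (defaults 5 and 500, per-kind overridable). Counts
are sentence-level document frequencies, matching the binary presence
semantics. The occurrence floor of five follows the original methodology;
the ceiling, reported there only as "usually above 500" and found by trial
and error, defaults to 500 and is fully configurable.

### The joint word–label embedding

The SD feature needs words and labels in one vector space. We build the
word × label co-occurrence matrix over labelled sentences (a label acts as
a pseudo-token in the context of every non-stop word of its sentence),
reweight it to positive pointwise mutual information, and factorize by
truncated SVD; word vectors are `U_d S_d^{1/2}`, label vectors
`V_d S_d^{1/2}`. This deterministic spectral factorization is the classic
closed-form counterpart of shallow sampled-softmax embedding trainers: it
needs no learning rate, epochs or stochastic seed, which makes model
artifacts exactly reproducible. The dimension defaults to 100, capped at
the matrix rank (with 37 labels the effective cap is 37).

### Training the SVMs

The solver is a dual coordinate-descent method for the L1-loss (hinge)
linear SVM with per-instance costs, the standard algorithm for linear SVMs
on sparse data. It visits instances in a seeded random permutation and
stops when the projected-gradient spread falls below `1e-3` or after 300
epochs; for the binary, highly sparse design matrices used here that cap is
far past convergence. The cost parameter `C` is either fixed (default 1)
or selected per node by inner cross-validation over the geometric grid
`{0.01, 0.1, 1, 10, 100}`.

## Evaluation

`nested_cv()` estimates generalization without contaminating the
hyperparameter choice: 4 outer folds (train on 75%, test on 25%) and,
inside each outer training portion, 5-fold inner cross-validation
(80%/20%) that picks `C` per node; outer-fold test predictions are pooled
into one report. Folds are grouped by abstract, not by sentence, so two
sentences of one abstract can never straddle a train/test boundary — the
sentences of an abstract share metadata and vocabulary, and sentence-level
folding would leak. Feature spaces and the embedding are rebuilt inside
every outer training portion; within the inner loop the outer-portion
feature spaces are reused, which keeps the inner loop honest about `C`
while avoiding a quadratic rebuild cost.

Metrics are the standard four — precision, recall, F1, accuracy — reported
in percent per node, macro-averaged (unweighted mean over nodes) and
micro-averaged (recomputed from pooled confusion counts; pooling is over
node counts). Ratios with a zero denominator are reported as 0 and
flagged. `ablate_features()` reruns the nested CV once per feature kind
with that kind removed, under identical fold assignments, and reports the
macro-F1 drop per kind. `cohen_kappa()` reduces multi-label agreement to
the unweighted mean of per-node binary kappas; nodes on which chance
agreement is 1 are excluded and reported. An alternative subset-agreement
reduction was considered and rejected as too strict for 37 sparse labels.

## Query analytics

Over a classified collection, a query's hallmark profile is computed from
sentence-level co-occurrence counts `(N, n_q, n_h, n_hq)`:

* conditional probability `P(h|q) = n_hq / n_q`,
* `PMI = log [P(h,q) / (P(h) P(q))]` in natural log (NPMI is base-invariant,
  raw PMI values are nats),
* `NPMI = PMI / (-log P(h,q))`, bounded in `[-1, 1]`.

Undefined values (zero counts; NPMI at `P(h,q) = 1`) are first-class `NA`s,
not errors. Query matching is case-insensitive contiguous token-phrase
matching — predictable and testable; stemming and synonym expansion are
deliberate non-features with a pluggable tokenizer as the extension point.
`P(h)` is estimated over the whole collection, not query-restricted
subsets.

Two queries are compared per node by a 2×2 table (query A/B × hallmark
present/absent). The expected-frequency rule routes the table: if any of
the four expected counts (row total × column total / N) is below five,
Fisher's exact test (two-sided, point-probability method) is used,
otherwise Pearson's chi-squared with one degree of freedom and no
continuity correction. P-values are Bonferroni-corrected by the number of
nodes in the comparison (37 for the full taxonomy). Sentences matching
both queries are counted in both rows and flagged in the output. Fisher's
test is implemented directly from the hypergeometric distribution (with
the conventional `1 + 1e-7` relative tolerance for floating-point ties) so
that its agreement with exact enumeration can be asserted to `1e-12`;
`stats::fisher.test` serves as an additional cross-check in the tests.

## Synthetic corpora

Real hallmark-annotated corpora and external biomedical taggers cannot be
bundled, so the package generates corpora with the statistical structure
that matters for testing:

* `generate_corpus()` emulates the annotated corpus: 75% unlabeled
  sentences; labelled sentences usually carry two labels because a
  subclass annotation implies its parent (probability-1 hypernym closure),
  with a small fraction (3.6% of labelled sentences) carrying exactly one
  top-level label and extra independent labels spreading the remaining
  mass — mirroring the published label-count distribution's shape;
  class-specific keyword vocabularies; abstract-level MeSH/chemical
  metadata correlated with contained labels. Text is space-joined word
  tokens with lemma = token; no grammar, no realistic English.
* `generate_separable_corpus()` gives every node a disjoint signature
  vocabulary and every sentence at least two signature words per carried
  label, making each node linearly separable by construction — the ideal
  parameter-recovery fixture.

Passing tests on these corpora demonstrate that the pipeline recovers
structure that is present (and finds nothing when labels are shuffled);
they say nothing about performance on real prose, which depends on the
segmenter, lemmatizer and entity tagger plugged in.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use a 2000-sentence separable
corpus for the nested-CV recovery check (macro-F1 over all 37 nodes is
expected at or near 100, asserted at ≥ 90) and a 740-sentence corpus for
the eight-run ablation; these sizes give stable estimates while keeping a
full run in minutes on one CPU. Degenerate inputs are handled explicitly:
empty corpora and empty queries raise errors; nodes with fewer positives
than folds are excluded from cross-validation with a warning recorded in
the report; classifiers are skipped (with a warning) for nodes with fewer
than `min_positives = 2` closed positives; zero-margin ties in the
expected-frequency rule go to the chi-squared side (`expected = 5` is not
"less than five").

## Known limitations

* The default lemmatizer is a lower-casing inflection stripper and the
  default entity tagger a gazetteer; both are stand-ins whose interfaces
  accept production components, and the model artifact records which
  components produced it.
* Gold labels are stored exactly as annotated; closure happens at training
  time. Corpora annotated with pre-closed label sets are therefore handled
  identically, but mixing conventions within one file is undetectable.
* The micro-average pools per-node confusion counts; pooling over
  sentence-level label sets would give different numbers.
* Raw absolute performance on a real annotated corpus depends on external
  NLP components and is out of scope for the bundled tests.
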