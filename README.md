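# hallmarker

Sentence-level classification of biomedical literature by the **Hallmarks of
Cancer**, plus association analytics over the classified collection.

The Hallmarks of Cancer describe the capabilities a cell acquires on the way
to malignancy (sustaining proliferative signalling, resisting cell death,
inducing angiogenesis, …). `hallmarker` assigns each sentence of a
MEDLINE/PubMed abstract any subset of a 37-node hallmark taxonomy — the ten
hallmarks and 27 process subclasses — and then lets you ask which hallmarks
the literature associates with a free-text query, or whether two queries
(two drugs, two genes) have different hallmark profiles.

## The model

One binary linear SVM per taxonomy node (one-vs-rest, so labels are not
mutually exclusive), trained on sparse binary feature vectors built from
seven feature families: lemmatized bag of words, token bi/trigrams, verb
classes, named entities, MeSH descriptors, chemical lists, and a
semantic-distance feature derived from a jointly trained word–label
embedding. Three structural ingredients:

* **hypernym closure** — a sentence labelled with a subclass (say `3.1`
  apoptosis) counts as a positive for its parent (`3` resisting cell death)
  during training;
* **inverse-proportional class weighting** — `w_c = N / (2 n_c)` compensates
  the rarity of positives;
* **parent-favoring post-processing** — a top-down pass makes the 37
  independent decisions hierarchy-consistent by suppressing any positive
  whose parent is negative.

Per-node feature selection keeps keys occurring in abstracts annotated with
the node and with corpus-wide sentence frequency in `[5, 500]`. Evaluation
is nested cross-validation (4 outer folds, 5 inner folds tuning the SVM cost
per node), reported as per-node precision/recall/F1/accuracy with macro and
micro averages.

The analytics layer computes, per node, co-occurrence counts between a
query's matched sentences and the node's label, conditional probability
`P(h|q)`, PMI and NPMI (natural log), and compares two queries per node with
Fisher's exact test or the chi-squared test — Fisher whenever an expected
cell count is below five — followed by Bonferroni correction.

## A worked example

Everything below runs offline: the package ships a seeded synthetic-corpus
generator that emulates the statistical structure of the real annotated
corpus (about 75% unlabeled sentences, hypernym-coupled multi-labels,
class-specific vocabulary, label-correlated abstract metadata).

```r
library(hallmarker)

tax <- hoc_taxonomy()
tax
#> Hallmark taxonomy: 37 nodes (10 top-level)
#> 1 Sustaining proliferative signalling
#>   1.1 Cell cycle
#> ...

## train on a separable synthetic corpus and evaluate by nested CV
corpus <- generate_separable_corpus(tax, n = 2000, seed = 42)
ev <- nested_cv(corpus, tax, hoc_control(tune_C = TRUE, seed = 42))
ev
#> Evaluation over 37 nodes
#>   macro: P 100.0  R 100.0  F1 100.0  Acc 100.0
#>   micro: P 100.0  R 100.0  F1 100.0  Acc 100.0
```

The separable corpus gives every node its own signature vocabulary, so a
correct pipeline must recover essentially perfect scores — a parameter
recovery check, not a claim about real text.

```r
## train on a realistic synthetic corpus, classify new text, query it
train_gen <- generate_corpus(synthetic_spec(n_abstracts = 400, seed = 2))
model <- hoc_train(train_gen$corpus, tax, hoc_control(seed = 2, min_count = 3))
model
#> Hallmark sentence classifier: 37/37 node models trained
#>   feature kinds: LBOW, NGRAM, VC, NE, MESH, CHEM, SD
#>   embedding: 622 words, dimension 37

new_gen <- generate_corpus(synthetic_spec(n_abstracts = 50, seed = 1))
preds <- predict(model, new_gen$corpus)
preds
#> Predictions for 294 sentences; 75 (25.5%) assigned >=1 hallmark

sents <- new_gen$corpus
sents$pred <- preds$final
assoc <- hallmark_associations(sents, "hm3kw1")  # a resisting-cell-death keyword
head(assoc[order(-assoc$npmi), c("code", "name", "n_q", "n_hq", "cprob", "npmi")], 4)
#>    code                 name n_q n_hq cprob  npmi
#> 10    3 Resisting cell death   8    8  1.00 0.967
#> 11  3.1            Apoptosis   8    2  0.25 0.722
#> 12  3.2            Autophagy   8    2  0.25 0.722
#> 13  3.3             Necrosis   8    2  0.25 0.641
```

All eight sentences containing the class keyword are classified with the
matching hallmark (`cprob` — the share of query-matching sentences carrying
the label — is 1.0), and its subclasses co-occur partially. `npmi` is
normalized pointwise mutual information (1 = perfect co-occurrence, 0 =
independence, negative = avoidance).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/hallmarker.R simulate --out corpus.tsv --n-abstracts 100 --seed 7
Rscript inst/cli/hallmarker.R train    --corpus corpus.tsv --model model/
Rscript inst/cli/hallmarker.R classify --model model/ --xml corpus.xml --out preds.tsv
Rscript inst/cli/hallmarker.R query    --predictions preds.tsv --query "p53" --out assoc
Rscript inst/cli/hallmarker.R compare  --predictions preds.tsv --query "egf" --query2 "vegf" --out cmp
```

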