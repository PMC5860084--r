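test_that("lemmatized bag-of-words has set semantics and drops stopwords", {
  sw <- hoc_stopwords()
  expect_setequal(extract_lbow(c("cell", "cycle", "arrest", "arrest"), sw),
                  c("LBOW:cell", "LBOW:cycle", "LBOW:arrest"))
  expect_length(extract_lbow(c("the", "of", "and"), sw), 0L)
  expect_equal(extract_lbow("P53", sw), "LBOW:p53")
})

test_that("n-gram enumeration produces all contiguous bigrams and trigrams", {
  expect_setequal(extract_ngrams(c("a", "b", "c")),
                  c("NGRAM:a_b", "NGRAM:b_c", "NGRAM:a_b_c"))
  expect_length(extract_ngrams("a"), 0L)
  expect_length(extract_ngrams(c("a", "b", "c", "d")), 5L)  # 3 + 2
  set.seed(7)
  for (i in 1:15) {
    n <- sample(0:12, 1)
    toks <- replicate(n, paste(sample(letters, 6), collapse = ""))
    expect_length(extract_ngrams(toks), max(0, n - 1) + max(0, n - 2))
  }
})

test_that("verb-class lookup groups predicates and deduplicates classes", {
  lex <- list(induce = "VC7", trigger = "VC7", block = "VC2")
  expect_equal(extract_verb_classes(c("induce", "cell"), lex), "VC:VC7")
  expect_length(extract_verb_classes(c("cell", "growth"), lex), 0L)
  expect_equal(extract_verb_classes(c("induce", "trigger"), lex), "VC:VC7")
  shipped <- read_verb_lexicon()
  expect_true("induce" %in% names(shipped))
})

test_that("entity features emit bare-type and type:surface keys", {
  tagger <- make_gazetteer_tagger(list(Protein = c("p53", "kras")))
  expect_setequal(extract_entities(c("p53", "binds"), tagger),
                  c("NE:Protein", "NE:Protein:p53"))
  expect_length(extract_entities(c("no", "entity"), tagger), 0L)
  expect_setequal(extract_entities(c("p53", "and", "KRAS"), tagger),
                  c("NE:Protein", "NE:Protein:p53", "NE:Protein:kras"))
  broken <- function(tokens) "O"
  expect_error(extract_entities(c("a", "b"), broken), "contract")
})

test_that("metadata features inherit MeSH and chemical descriptors", {
  expect_setequal(extract_metadata("Lung Neoplasms", "Cisplatin"),
                  c("MESH:Lung Neoplasms", "CHEM:Cisplatin"))
  expect_length(extract_metadata(character(0), character(0)), 0L)
  expect_length(extract_metadata(c("Mice", "Mice"), character(0)), 1L)
})

test_that("semantic-distance keys discretize the max cosine into bins", {
  emb <- toy_embedding()
  # identical direction -> cosine 1 -> top bin
  expect_equal(extract_semantic_distance("wa", emb, "1", bins = 10),
               "SD:bin10")
  # orthogonal only -> cosine 0 -> the bin containing zero
  expect_equal(extract_semantic_distance("wb", emb, "1", bins = 10),
               "SD:bin06")
  # no in-vocabulary lemma, or only zero vectors: no key
  expect_length(extract_semantic_distance("unknown", emb, "1"), 0L)
  expect_length(extract_semantic_distance("wz", emb, "1"), 0L)
  expect_error(extract_semantic_distance("wa", emb, "9.9"), "not in embedding")
  # bins partition [-1, 1]: every similarity maps to exactly one bin
  for (s in c(-1, -0.999, -0.2, 0, 0.1999, 0.2, 0.999, 1)) {
    b <- hallmarker:::sd_bin(s, 10L)
    expect_match(b, "^bin(0[1-9]|10)$")
    lo <- -1 + 2 * (as.integer(sub("bin", "", b)) - 1) / 10
    expect_true(s >= lo - 1e-12 && s <= lo + 0.2 + 1e-12)
  }
})

test_that("per-class selection keeps mid-frequency keys from positive abstracts", {
  tax <- hoc_taxonomy()
  # abstracts: A (positive for 3 via 3.1), B (negative)
  pm <- c(rep("A", 6), rep("B", 6))
  text <- c(rep("shared rare", 2), rep("shared common", 4),
            rep("negonly word", 2), rep("shared common", 4))
  gold <- c(list("3.1"), rep(list(character(0)), 11))
  corpus <- make_corpus(pm, text, gold)
  cfg <- feature_config(kinds = "LBOW", stopwords = character(0))
  space <- select_features(corpus, "3", tax, cfg, min_count = 5L,
                           max_count = 500L)
  # "shared" occurs 12x, "common" 8x, "rare" 2x (below min), "negonly" only
  # in the negative abstract
  expect_setequal(space$keys, c("LBOW:shared", "LBOW:common"))
  # boundary: exactly min_count occurrences ("common" has 8) is kept,
  # one more excludes it
  space4 <- select_features(corpus, "3", tax, cfg, min_count = 8L)
  expect_setequal(space4$keys, c("LBOW:common", "LBOW:shared"))
  space4b <- select_features(corpus, "3", tax, cfg, min_count = 9L)
  expect_equal(space4b$keys, "LBOW:shared")
  # max_count excludes too-common keys ("shared" has 10)
  space5 <- select_features(corpus, "3", tax, cfg, min_count = 1L,
                            max_count = 9L)
  expect_false("LBOW:shared" %in% space5$keys)
  expect_error(select_features(corpus, "5", tax, cfg), "no positive")
})

test_that("selection with no thresholds equals the brute-force positive-key set", {
  tax <- hoc_taxonomy()
  set.seed(31)
  vocab <- paste0("w", 1:40)
  pm <- rep(paste0("A", 1:10), each = 3)
  text <- replicate(30, paste(sample(vocab, 5), collapse = " "))
  gold <- lapply(1:30, function(i)
    if (i %% 4 == 0) sample(tax$code, 1) else character(0))
  corpus <- make_corpus(pm, text, gold)
  cfg <- feature_config(kinds = "LBOW", stopwords = character(0))
  closed <- lapply(corpus$gold, closure_labels, taxonomy = tax)
  for (code in unique(unlist(closed))) {
    pos_pm <- unique(pm[vapply(closed, function(g) code %in% g, logical(1))])
    oracle <- sort(unique(unlist(
      lapply(which(pm %in% pos_pm), function(i)
        extract_lbow(corpus$lemmas[[i]], character(0))))))
    space <- select_features(corpus, code, tax, cfg, min_count = 1L,
                             max_count = Inf)
    expect_equal(space$keys, oracle)
  }
})

test_that("vectorization is deterministic and equals the per-extractor union", {
  tax <- hoc_taxonomy()
  lex <- list(induce = "VC1")
  tagger <- make_gazetteer_tagger(list(Protein = "p53"))
  corpus <- make_corpus(
    c("A", "A", "B", "B"),
    c("p53 induce apoptosis signal", "apoptosis signal decay",
      "growth factor signal", "p53 decay induce"),
    gold = list("3.1", "3.1", character(0), character(0)),
    mesh = list("Apoptosis", "Apoptosis", character(0), character(0)),
    chem = rep(list(character(0)), 4))
  cfg <- feature_config(kinds = c("LBOW", "NGRAM", "VC", "NE", "MESH"),
                        stopwords = character(0), lexicon = lex,
                        tagger = tagger)
  space <- select_features(corpus, "3", tax, cfg, min_count = 1L,
                           max_count = Inf)
  X1 <- vectorize_corpus(corpus, space, cfg)
  X2 <- vectorize_corpus(corpus, space, cfg)
  expect_identical(as.matrix(X1), as.matrix(X2))
  expect_true(all(X1@x == 1))
  # union of single-kind extractions reproduces the full design matrix
  union <- Reduce(`+`, lapply(c("LBOW", "NGRAM", "VC", "NE", "MESH"),
    function(kind) {
      ck <- feature_config(kinds = kind, stopwords = character(0),
                           lexicon = lex, tagger = tagger)
      as.matrix(vectorize_corpus(corpus, space, ck))
    }))
  expect_identical(as.matrix(X1), (union > 0) + 0)
  # a sentence with only unindexed keys gives an all-zero row of full width
  alien <- make_corpus("Z", "totally unrelated words")
  X3 <- vectorize_corpus(alien, space, cfg)
  expect_equal(dim(X3), c(1L, length(space$keys)))
  expect_equal(sum(X3), 0)
})

test_that("feature spaces serialize to JSON and back", {
  space <- structure(list(code = "3.1",
                          keys = c("LBOW:apoptosis", "NE:Protein:p53",
                                   "SD:bin09"),
                          min_count = 5L, max_count = 500L),
                     class = "hoc_feature_space")
  f <- withr::local_tempfile(fileext = ".json")
  write_feature_space(space, f)
  back <- read_feature_space(f)
  expect_equal(back$code, space$code)
  expect_equal(back$keys, space$keys)
  expect_equal(back$min_count, space$min_count)
})
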