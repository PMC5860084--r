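# Feature keys are strings "KIND:value" with KIND one of
# LBOW, NGRAM, VC, NE, MESH, CHEM, SD; only the first colon separates.

FEATURE_KINDS <- c("LBOW", "NGRAM", "VC", "NE", "MESH", "CHEM", "SD")

key_kind <- function(keys) sub(":.*$", "", keys)

#' Feature extraction configuration
#'
#' Bundles the resources and switches shared by the seven feature extractors.
#' Any subset of kinds can be enabled; `VC`, `NE` and `SD` are silently
#' inactive when their resource (lexicon, tagger, embedding) is absent.
#'
#' @param kinds character vector of enabled feature kinds (subset of
#'   `LBOW`, `NGRAM`, `VC`, `NE`, `MESH`, `CHEM`, `SD`).
#' @param stopwords lower-case stopword vector used by `LBOW` and the
#'   embedding; defaults to the shipped list.
#' @param lexicon verb-class lexicon from [read_verb_lexicon()], or `NULL`.
#' @param tagger an entity tagger (`function(tokens) -> tags`), or `NULL`.
#' @param embedding an `hoc_embedding` for the semantic-distance feature, or
#'   `NULL`.
#' @param sd_bins number of equal-width discretization bins over `[-1, 1]`
#'   for the semantic-distance cosine.
#' @return A `feature_config` list.
#' @export
feature_config <- function(kinds = FEATURE_KINDS,
                           stopwords = hoc_stopwords(),
                           lexicon = NULL, tagger = NULL, embedding = NULL,
                           sd_bins = 10L) {
  stopifnot(all(kinds %in% FEATURE_KINDS), sd_bins >= 1L)
  structure(list(kinds = kinds, stopwords = stopwords, lexicon = lexicon,
                 tagger = tagger, embedding = embedding,
                 sd_bins = as.integer(sd_bins)),
            class = "feature_config")
}

#' Lemmatized bag-of-words features
#'
#' One key per distinct non-stopword lemma, lower-cased.
#'
#' @param lemmas character vector of sentence lemmas.
#' @param stopwords lower-case stopword list.
#' @return Character vector of `LBOW:` keys.
#' @export
extract_lbow <- function(lemmas, stopwords = hoc_stopwords()) {
  if (is.null(lemmas)) stop("lemmas not populated", call. = FALSE)
  w <- setdiff(unique(tolower(lemmas)), stopwords)
  if (!length(w)) return(character(0))
  paste0("LBOW:", w)
}

#' Token bigram and trigram features
#'
#' All contiguous bigrams and trigrams over the token sequence, joined with
#' `_`.
#'
#' @param tokens character vector of sentence tokens.
#' @return Character vector of `NGRAM:` keys (deduplicated).
#' @export
extract_ngrams <- function(tokens) {
  n <- length(tokens)
  out <- character(0)
  if (n >= 2L)
    out <- paste0(tokens[-n], "_", tokens[-1L])
  if (n >= 3L)
    out <- c(out, paste0(tokens[1:(n - 2L)], "_", tokens[2:(n - 1L)], "_",
                         tokens[3:n]))
  if (!length(out)) return(character(0))
  paste0("NGRAM:", unique(out))
}

#' Verb-class features
#'
#' One key per verb class matched by any sentence lemma in the lexicon;
#' grouping semantically similar predicates abstracts away from individual
#' verbs under data sparsity.
#'
#' @param lemmas character vector of sentence lemmas.
#' @param lexicon a verb-class lexicon from [read_verb_lexicon()].
#' @return Character vector of `VC:` keys.
#' @export
extract_verb_classes <- function(lemmas, lexicon) {
  if (is.null(lexicon)) return(character(0))
  hits <- unlist(lexicon[intersect(tolower(lemmas), names(lexicon))],
                 use.names = FALSE)
  if (!length(hits)) return(character(0))
  paste0("VC:", unique(hits))
}

#' Named-entity features
#'
#' Tags tokens with one of the five entity types relevant to cancer research
#' (Protein, DNA, RNA, Cell_line, Cell_type) or `O`, and emits both a
#' bare-type key and a type:surface key per tagged token.
#'
#' @param tokens character vector of sentence tokens.
#' @param tagger `function(tokens) -> tags`, same length, values in the five
#'   types or `"O"`.
#' @return Character vector of `NE:` keys.
#' @export
extract_entities <- function(tokens, tagger) {
  if (is.null(tagger) || !length(tokens)) return(character(0))
  tags <- tagger(tokens)
  if (length(tags) != length(tokens))
    stop("entity tagger contract violated: output length ", length(tags),
         " != input length ", length(tokens), call. = FALSE)
  hit <- tags != "O"
  if (!any(hit)) return(character(0))
  keys <- c(paste0("NE:", tags[hit]),
            paste0("NE:", tags[hit], ":", tolower(tokens[hit])))
  unique(keys)
}

#' Abstract-metadata features
#'
#' One key per inherited MeSH descriptor and one per chemical-substance name.
#'
#' @param mesh,chem character vectors inherited from the parent abstract.
#' @return Character vector of `MESH:`/`CHEM:` keys.
#' @export
extract_metadata <- function(mesh, chem) {
  c(if (length(mesh)) paste0("MESH:", unique(mesh)),
    if (length(chem)) paste0("CHEM:", unique(chem)))
}

#' Semantic-distance feature
#'
#' Maximum cosine similarity between the sentence's in-vocabulary lemmas and
#' the label vector of `code` in the joint word-label embedding, discretized
#' into `bins` equal-width bins over `[-1, 1]` and emitted as one binary
#' indicator key. Sentences with no in-vocabulary lemma emit nothing.
#'
#' @param lemmas character vector of sentence lemmas.
#' @param embedding an `hoc_embedding`.
#' @param code taxonomy node code whose label vector is used.
#' @param bins number of bins.
#' @return Character vector with zero or one `SD:` key.
#' @export
extract_semantic_distance <- function(lemmas, embedding, code, bins = 10L) {
  if (is.null(embedding)) return(character(0))
  if (!code %in% rownames(embedding$label_vectors))
    stop("code not in embedding: ", code, call. = FALSE)
  lv <- embedding$label_vectors[code, ]
  lnorm <- sqrt(sum(lv^2))
  if (lnorm == 0) return(character(0))
  lemmas <- unique(tolower(lemmas))
  inv <- intersect(lemmas, rownames(embedding$word_vectors))
  if (!length(inv)) return(character(0))
  W <- embedding$word_vectors[inv, , drop = FALSE]
  wn <- sqrt(rowSums(W^2))
  ok <- wn > 0
  if (!any(ok)) return(character(0))
  sim <- max((W[ok, , drop = FALSE] %*% lv) / (wn[ok] * lnorm))
  paste0("SD:", sd_bin(sim, bins))
}

# Equal-width bins over [-1,1]; bin b covers [-1 + 2(b-1)/B, -1 + 2b/B),
# with the right edge closed for the last bin so the bins partition [-1,1].
sd_bin <- function(sim, bins) {
  b <- floor((sim + 1) / 2 * bins) + 1L
  b <- max(1L, min(as.integer(bins), b))
  sprintf("bin%02d", b)
}

#' All feature keys of every sentence
#'
#' Runs the enabled extractors over a corpus. The semantic-distance feature
#' is class-specific: it is only produced when `code` is given (the node
#' whose feature space is being built or filled).
#'
#' @param corpus an `hoc_corpus`.
#' @param config a [feature_config()].
#' @param code taxonomy node code for the `SD` feature, or `NULL`.
#' @return List (one element per sentence) of character key vectors.
#' @export
sentence_keys <- function(corpus, config, code = NULL) {
  kinds <- config$kinds
  lapply(seq_len(nrow(corpus)), function(k) {
    keys <- character(0)
    if ("LBOW" %in% kinds)
      keys <- c(keys, extract_lbow(corpus$lemmas[[k]], config$stopwords))
    if ("NGRAM" %in% kinds)
      keys <- c(keys, extract_ngrams(corpus$tokens[[k]]))
    if ("VC" %in% kinds && !is.null(config$lexicon))
      keys <- c(keys, extract_verb_classes(corpus$lemmas[[k]], config$lexicon))
    if ("NE" %in% kinds && !is.null(config$tagger))
      keys <- c(keys, extract_entities(corpus$tokens[[k]], config$tagger))
    if (any(c("MESH", "CHEM") %in% kinds)) {
      md <- extract_metadata(if ("MESH" %in% kinds) corpus$mesh[[k]] else character(0),
                             if ("CHEM" %in% kinds) corpus$chem[[k]] else character(0))
      keys <- c(keys, md)
    }
    if ("SD" %in% kinds && !is.null(config$embedding) && !is.null(code))
      keys <- c(keys, extract_semantic_distance(corpus$lemmas[[k]],
                                                config$embedding, code,
                                                config$sd_bins))
    keys
  })
}

#' Per-class feature selection
#'
#' Builds the feature space of one taxonomy node. Candidate keys are those
#' occurring in at least one sentence of an abstract annotated (after
#' hypernym closure) with the node; a candidate is kept iff its corpus-wide
#' sentence document frequency lies in `[min_count, max_count(kind)]`.
#' Features too rare or too common are thereby filtered out, and each
#' classifier gets its own discriminating feature set.
#'
#' @param corpus an `hoc_corpus` with gold labels.
#' @param code taxonomy node code.
#' @param taxonomy an `hoc_taxonomy`.
#' @param config a [feature_config()].
#' @param min_count minimum sentence occurrence count (inclusive).
#' @param max_count maximum occurrence count; a single number or a named
#'   vector per feature kind.
#' @param keys optional precomputed `sentence_keys(corpus, config, code)`.
#' @param positive_pmids optional precomputed pmids of abstracts positive for
#'   `code` after closure (avoids recomputing the closure per node).
#' @param key_counts optional precomputed corpus-wide sentence occurrence
#'   counts (a `table` over all keys).
#' @return An `hoc_feature_space`: list with `code`, `keys` (column order),
#'   `min_count`, `max_count`.
#' @export
select_features <- function(corpus, code, taxonomy, config,
                            min_count = 5L, max_count = 500L, keys = NULL,
                            positive_pmids = NULL, key_counts = NULL) {
  if (!nrow(corpus)) stop("empty corpus", call. = FALSE)
  if (is.null(keys)) keys <- sentence_keys(corpus, config, code)
  pos_pmids <- positive_pmids
  if (is.null(pos_pmids)) {
    closed <- lapply(corpus$gold, closure_labels, taxonomy = taxonomy)
    pos_pmids <- unique(corpus$pmid[vapply(closed, function(g) code %in% g,
                                           logical(1))])
  }
  if (!length(pos_pmids))
    stop("no positive sentences for node ", code, call. = FALSE)
  cand <- unique(unlist(keys[corpus$pmid %in% pos_pmids], use.names = FALSE))
  counts <- if (is.null(key_counts)) table(unlist(keys, use.names = FALSE))
            else key_counts
  cnt <- as.integer(counts[cand])
  kind <- key_kind(cand)
  maxk <- if (is.null(names(max_count))) rep(max_count, length(cand)) else {
    m <- max_count[kind]
    m[is.na(m)] <- Inf
    as.numeric(m)
  }
  keep <- cnt >= min_count & cnt <= maxk
  space <- list(code = code, keys = sort(cand[keep]),
                min_count = min_count, max_count = max_count)
  class(space) <- "hoc_feature_space"
  space
}

#' Vectorize sentences into a sparse binary design matrix
#'
#' Active columns of each sentence are exactly its indexed keys; keys outside
#' the space are silently dropped. Values are implicitly 1 (sparse binary
#' representation).
#'
#' @param corpus an `hoc_corpus`.
#' @param space an `hoc_feature_space`.
#' @param config a [feature_config()].
#' @param keys optional precomputed `sentence_keys(corpus, config, space$code)`.
#' @return A `dgCMatrix` of dimension `nrow(corpus) x length(space$keys)`.
#' @export
vectorize_corpus <- function(corpus, space, config, keys = NULL) {
  if (is.null(keys)) keys <- sentence_keys(corpus, config, space$code)
  cols <- lapply(keys, function(k) {
    j <- match(unique(k), space$keys)
    j[!is.na(j)]
  })
  i <- rep(seq_along(cols), lengths(cols))
  j <- unlist(cols, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(corpus), length(space$keys)),
                       dimnames = list(NULL, space$keys))
}

#' Read a verb-class lexicon
#'
#' TSV with header `lemma<TAB>class_id`, one row per (lemma, class) pair;
#' a lemma may belong to several classes.
#'
#' @param path file path; defaults to the small synthetic lexicon shipped for
#'   testing (a stand-in for an externally induced verb clustering).
#' @return Named list: lower-case lemma -> character vector of class ids.
#' @export
read_verb_lexicon <- function(path = system.file("extdata",
                                                 "verb_classes_synthetic.tsv",
                                                 package = "hallmarker")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("lemma", "class_id") %in% names(df)))
  split(as.character(df$class_id), tolower(df$lemma))
}

#' Gazetteer entity tagger
#'
#' A simple dictionary tagger over per-type term lists, intended for tests
#' and small-scale runs; a production system would plug in an external
#' biomedical named-entity tagger through the same `function(tokens) -> tags`
#' contract. Matching is case-insensitive on single tokens; the first type
#' listing a term wins.
#'
#' @param lists named list of character term vectors; names are entity types
#'   (conventionally Protein, DNA, RNA, Cell_line, Cell_type). Default: the
#'   shipped synthetic gazetteer.
#' @return A tagger function.
#' @export
make_gazetteer_tagger <- function(lists = default_gazetteer()) {
  types <- rep(names(lists), lengths(lists))
  terms <- tolower(unlist(lists, use.names = FALSE))
  dup <- duplicated(terms)
  terms <- terms[!dup]; types <- types[!dup]
  function(tokens) {
    m <- match(tolower(tokens), terms)
    out <- ifelse(is.na(m), "O", types[m])
    as.character(out)
  }
}

#' @rdname make_gazetteer_tagger
#' @export
default_gazetteer <- function() {
  dir <- system.file("extdata", "gazetteer_synthetic", package = "hallmarker")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  lists <- lapply(files, readLines, encoding = "UTF-8", warn = FALSE)
  names(lists) <- sub("\\.txt$", "", basename(files))
  lists
}

#' Serialize / load a feature space
#'
#' JSON artifact listing kind, value and column for every indexed key.
#'
#' @param space an `hoc_feature_space`.
#' @param path file path.
#' @export
write_feature_space <- function(space, path) {
  obj <- list(code = space$code, min_count = space$min_count,
              max_count = space$max_count,
              keys = data.frame(kind = key_kind(space$keys),
                                value = sub("^[A-Z]+:", "", space$keys),
                                column = seq_along(space$keys) - 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- if (length(obj$keys)) paste0(obj$keys$kind, ":", obj$keys$value)
          else character(0)
  mx <- obj$max_count
  if (!is.null(names(mx)) && length(names(mx))) mx <- unlist(mx)
  space <- list(code = obj$code, keys = keys,
                min_count = obj$min_count, max_count = mx)
  class(space) <- "hoc_feature_space"
  space
}
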