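#' Train the joint word-label embedding
#'
#' Builds a vector space in which sentence words and taxonomy labels live
#' together, so that cosine similarity between a word and a label measures
#' their semantic association. Labels are treated as pseudo-tokens occurring
#' in the context of every (non-stop) word of each labelled sentence; the
#' word-label co-occurrence matrix is reweighted to positive pointwise mutual
#' information and factorized by truncated SVD. Word vectors are
#' `U_d sqrt(S_d)` and label vectors `V_d sqrt(S_d)`, a deterministic shallow
#' factorization known to approximate the solution of sampled-softmax
#' skip-gram training.
#'
#' @param corpus an `hoc_corpus` with at least one labelled sentence.
#' @param taxonomy an `hoc_taxonomy`; labels are closed over ancestors so
#'   subclass evidence also counts toward parent labels.
#' @param dimension target dimension `d`; capped at the matrix rank.
#' @param stopwords words excluded from the vocabulary.
#' @param min_word_count vocabulary floor (sentence frequency).
#' @param seed recorded in the config for provenance; the factorization
#'   itself is deterministic.
#' @return An `hoc_embedding`: list with `dimension`, `word_vectors`
#'   (vocab x d matrix), `label_vectors` (labels x d), `config`.
#' @export
train_embedding <- function(corpus, taxonomy, dimension = 100L,
                            stopwords = hoc_stopwords(),
                            min_word_count = 2L, seed = 1L) {
  closed <- lapply(corpus$gold, closure_labels, taxonomy = taxonomy)
  labelled <- lengths(closed) > 0L
  if (!any(labelled))
    stop("embedding requires at least one labelled sentence", call. = FALSE)
  words <- lapply(corpus$lemmas[labelled], function(l)
    setdiff(unique(tolower(l)), stopwords))
  labs <- closed[labelled]
  wc <- table(unlist(words, use.names = FALSE))
  vocab <- sort(names(wc[wc >= min_word_count]))
  labels <- sort(unique(unlist(labs, use.names = FALSE)))
  if (!length(vocab)) stop("empty embedding vocabulary", call. = FALSE)
  # word x label co-occurrence within labelled sentences
  wi <- unlist(lapply(seq_along(words), function(k) {
    w <- match(words[[k]], vocab)
    w <- w[!is.na(w)]
    rep(w, each = length(labs[[k]]))
  }), use.names = FALSE)
  li <- unlist(lapply(seq_along(words), function(k) {
    w <- match(words[[k]], vocab)
    rep(match(labs[[k]], labels), times = sum(!is.na(w)))
  }), use.names = FALSE)
  C <- as.matrix(Matrix::sparseMatrix(i = wi, j = li, x = 1,
                                      dims = c(length(vocab), length(labels))))
  total <- sum(C)
  pw <- rowSums(C) / total
  pl <- colSums(C) / total
  pmi <- log((C / total) / outer(pw, pl))
  pmi[!is.finite(pmi) | pmi < 0] <- 0        # positive PMI
  d <- min(dimension, nrow(pmi), ncol(pmi))
  sv <- svd(pmi, nu = d, nv = d)
  scale <- sqrt(pmax(sv$d[seq_len(d)], 0))
  wv <- sv$u * rep(scale, each = nrow(pmi))
  lv <- sv$v * rep(scale, each = ncol(pmi))
  rownames(wv) <- vocab
  rownames(lv) <- labels
  emb <- list(dimension = d, word_vectors = wv, label_vectors = lv,
              config = list(dimension = as.integer(dimension),
                            min_word_count = as.integer(min_word_count),
                            method = "ppmi-svd", seed = as.integer(seed)))
  class(emb) <- "hoc_embedding"
  emb
}

#' Cosine similarity between a word and a label
#'
#' @param embedding an `hoc_embedding`.
#' @param lemma a word (lower-cased for lookup).
#' @param code a taxonomy node code.
#' @return Cosine in `[-1, 1]`, or `NA_real_` when either vector is out of
#'   vocabulary or zero (undefined similarity is a first-class value).
#' @export
embedding_similarity <- function(embedding, lemma, code) {
  lemma <- tolower(lemma)
  if (!lemma %in% rownames(embedding$word_vectors)) return(NA_real_)
  if (!code %in% rownames(embedding$label_vectors)) return(NA_real_)
  w <- embedding$word_vectors[lemma, ]
  l <- embedding$label_vectors[code, ]
  nw <- sqrt(sum(w^2)); nl <- sqrt(sum(l^2))
  if (nw == 0 || nl == 0) return(NA_real_)
  sum(w * l) / (nw * nl)
}

#' @export
print.hoc_embedding <- function(x, ...) {
  cat(sprintf("Joint word-label embedding: %d words, %d labels, dimension %d (%s)\n",
              nrow(x$word_vectors), nrow(x$label_vectors), x$dimension,
              x$config$method))
  invisible(x)
}

#' Save / load an embedding as a JSON artifact
#'
#' Plain-text artifact: config block, vocabulary tables and vector arrays.
#'
#' @param embedding an `hoc_embedding`.
#' @param path file path.
#' @export
write_embedding <- function(embedding, path) {
  obj <- list(dimension = embedding$dimension, config = embedding$config,
              words = rownames(embedding$word_vectors),
              labels = rownames(embedding$label_vectors),
              word_vectors = unname(embedding$word_vectors),
              label_vectors = unname(embedding$label_vectors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wv <- matrix(obj$word_vectors, nrow = length(obj$words))
  lv <- matrix(obj$label_vectors, nrow = length(obj$labels))
  rownames(wv) <- obj$words
  rownames(lv) <- obj$labels
  emb <- list(dimension = obj$dimension, word_vectors = wv,
              label_vectors = lv, config = obj$config)
  class(emb) <- "hoc_embedding"
  emb
}
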