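# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

code_token <- function(prefix, code, suffix = "") {
  if (!length(code)) return(character(0))
  paste0(prefix, gsub(".", "x", code, fixed = TRUE), suffix)
}

# uniform integer in [lo, hi]; safe when lo == hi (sample(6:6, 1) would
# otherwise draw from 1:6)
rint <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

#' Synthetic-corpus specification
#'
#' Parameters of the generator that emulates the statistical structure of the
#' sentence-level hallmark-annotated corpus: about 75\% of sentences carry no
#' label; labelled sentences usually carry two labels because annotating a
#' subclass implies its parent hallmark (hypernym coupling); each class has
#' its own keyword vocabulary; abstract-level MeSH/chemical metadata is
#' correlated with the labels inside the abstract.
#'
#' Label-count shape (defaults): a labelled sentence picks a primary node —
#' with probability `p_single_top` a top-level hallmark (exactly one label),
#' otherwise a subclass whose ancestor closure yields two or three labels —
#' and with probability `p_extra` an additional independent node, spreading
#' the remaining mass over three-plus-label sentences.
#'
#' @param n_abstracts number of abstracts.
#' @param sentences_per_abstract inclusive integer range `c(lo, hi)`.
#' @param p_unlabeled probability a sentence carries no label.
#' @param p_single_top probability a labelled sentence is labelled with
#'   exactly one top-level hallmark.
#' @param p_extra probability of one extra independent primary node.
#' @param label_marginals optional named inclusion weights over node codes
#'   for the primary draw (uniform when `NULL`).
#' @param vocab_per_class class-specific keyword types per node.
#' @param background_vocab background word types.
#' @param keyword_rate probability each keyword of a carried label appears.
#' @param words_per_sentence background-word count range `c(lo, hi)`.
#' @param metadata_rate probability a label of an abstract attaches its
#'   MeSH term and its chemical name to the abstract.
#' @param seed RNG seed; corpora are fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_abstracts = 250L,
                           sentences_per_abstract = c(4L, 8L),
                           p_unlabeled = 0.75, p_single_top = 0.036,
                           p_extra = 0.15, label_marginals = NULL,
                           vocab_per_class = 6L, background_vocab = 400L,
                           keyword_rate = 0.5,
                           words_per_sentence = c(6L, 12L),
                           metadata_rate = 0.5, seed = 42L) {
  stopifnot(p_unlabeled >= 0, p_unlabeled <= 1, keyword_rate >= 0,
            keyword_rate <= 1, metadata_rate >= 0, metadata_rate <= 1,
            n_abstracts >= 1, vocab_per_class >= 1, background_vocab >= 1)
  structure(list(n_abstracts = as.integer(n_abstracts),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 p_unlabeled = p_unlabeled, p_single_top = p_single_top,
                 p_extra = p_extra, label_marginals = label_marginals,
                 vocab_per_class = as.integer(vocab_per_class),
                 background_vocab = as.integer(background_vocab),
                 keyword_rate = keyword_rate,
                 words_per_sentence = as.integer(words_per_sentence),
                 metadata_rate = metadata_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic annotated corpus
#'
#' Draws abstracts of labelled and unlabeled sentences per
#' [synthetic_spec()]. Labelled sentences draw keywords from the
#' vocabularies of their classes on top of background words; labelling any
#' node always labels its ancestors (probability-1 hypernym closure in the
#' gold sets); abstract metadata (one MeSH descriptor and one chemical name
#' per class) is attached with probability `metadata_rate` for each label
#' present in the abstract.
#'
#' @param spec a [synthetic_spec()].
#' @param taxonomy an `hoc_taxonomy`.
#' @return List with `abstracts` (an `hoc_abstracts`) and `corpus` (an
#'   `hoc_corpus` with gold labels and inherited metadata).
#' @export
generate_corpus <- function(spec = synthetic_spec(),
                            taxonomy = hoc_taxonomy()) {
  with_seed(spec$seed, {
    codes <- taxonomy$code
    top <- codes[is.na(taxonomy$parent)]
    sub <- setdiff(codes, top)
    weights <- if (is.null(spec$label_marginals)) NULL
               else spec$label_marginals[sub]
    kw <- lapply(codes, function(code)
      code_token("hm", code, paste0("kw", seq_len(spec$vocab_per_class))))
    names(kw) <- codes
    bg <- sprintf("bg%03d", seq_len(spec$background_vocab))
    pm <- character(0); si <- integer(0); tx <- character(0)
    gold <- list(); ab_pmid <- character(0); ab_body <- character(0)
    ab_mesh <- list(); ab_chem <- list()
    for (a in seq_len(spec$n_abstracts)) {
      pmid <- sprintf("SYN%05d", a)
      ns <- rint(spec$sentences_per_abstract[1], spec$sentences_per_abstract[2])
      sents <- character(ns); labels <- vector("list", ns)
      for (s in seq_len(ns)) {
        labs <- character(0)
        if (stats::runif(1) >= spec$p_unlabeled) {
          primary <- if (stats::runif(1) < spec$p_single_top)
            sample(top, 1) else sample(sub, 1, prob = weights)
          labs <- closure_labels(primary, taxonomy)
          if (stats::runif(1) < spec$p_extra) {
            extra <- sample(codes, 1)
            labs <- closure_labels(c(labs, extra), taxonomy)
          }
        }
        nw <- rint(spec$words_per_sentence[1], spec$words_per_sentence[2])
        words <- sample(bg, nw, replace = TRUE)
        for (lb in labs) {
          pick <- stats::runif(spec$vocab_per_class) < spec$keyword_rate
          words <- c(words, kw[[lb]][pick])
        }
        words <- sample(words)
        sents[s] <- paste(words, collapse = " ")
        labels[[s]] <- labs
      }
      pm <- c(pm, rep(pmid, ns)); si <- c(si, seq_len(ns) - 1L)
      tx <- c(tx, sents); gold <- c(gold, labels)
      ab_labels <- unique(unlist(labels, use.names = FALSE))
      keep <- ab_labels[stats::runif(length(ab_labels)) < spec$metadata_rate]
      ab_pmid <- c(ab_pmid, pmid)
      body <- paste0(toupper(substring(sents, 1, 1)), substring(sents, 2),
                     ".", collapse = " ")
      ab_body <- c(ab_body, body)
      ab_mesh[[a]] <- if (length(keep)) code_token("MeSH term ", keep)
                      else character(0)
      ab_chem[[a]] <- if (length(keep)) code_token("Chemical ", keep)
                      else character(0)
    }
    abstracts <- data.frame(pmid = ab_pmid,
                            title = paste("Synthetic abstract", ab_pmid),
                            body = ab_body, stringsAsFactors = FALSE)
    abstracts$mesh <- ab_mesh
    abstracts$chem <- ab_chem
    class(abstracts) <- c("hoc_abstracts", "data.frame")
    tok <- lapply(tx, default_tokenizer)
    corpus <- new_corpus(pm, si, tx, tok, lapply(tok, tolower),
                         mesh = ab_mesh[match(pm, ab_pmid)],
                         chem = ab_chem[match(pm, ab_pmid)], gold = gold)
    list(abstracts = abstracts, corpus = corpus)
  })
}

#' Generate a linearly separable synthetic corpus
#'
#' Every node receives a disjoint signature vocabulary; each sentence is
#' assigned one primary node (abstracts of four sentences share a primary,
#' primaries cycle over all nodes so every node is populated) and carries at
#' least two signature words of each label in its ancestor closure, on top
#' of background words. Each node's positive set is therefore linearly
#' separable from its complement by construction.
#'
#' @param taxonomy an `hoc_taxonomy`.
#' @param n number of sentences (at least `10 * nrow(taxonomy)`).
#' @param seed RNG seed.
#' @param signature_size signature word types per node.
#' @param background_vocab background word types.
#' @return An `hoc_corpus` with gold labels (no metadata).
#' @export
generate_separable_corpus <- function(taxonomy = hoc_taxonomy(), n = 2000L,
                                      seed = 42L, signature_size = 4L,
                                      background_vocab = 200L) {
  stopifnot(n >= 10L * nrow(taxonomy))
  with_seed(seed, {
    codes <- taxonomy$code
    sig <- lapply(codes, function(code)
      code_token("sig", code, paste0("w", seq_len(signature_size))))
    names(sig) <- codes
    bg <- sprintf("bg%03d", seq_len(background_vocab))
    per_abs <- 4L
    n_abs <- ceiling(n / per_abs)
    primary_of_abs <- sample(rep_len(codes, n_abs))
    pm <- character(0); si <- integer(0); tx <- character(0); gold <- list()
    total <- 0L
    for (a in seq_len(n_abs)) {
      pmid <- sprintf("SEP%05d", a)
      labs <- closure_labels(primary_of_abs[a], taxonomy)
      ns <- min(per_abs, n - total)
      for (s in seq_len(ns)) {
        words <- sample(bg, rint(3L, 6L), replace = TRUE)
        for (lb in labs)
          words <- c(words, sample(sig[[lb]], rint(2L, 3L)))
        words <- sample(words)
        pm <- c(pm, pmid); si <- c(si, s - 1L)
        tx <- c(tx, paste(words, collapse = " "))
        gold <- c(gold, list(labs))
      }
      total <- total + ns
      if (total >= n) break
    }
    tok <- lapply(tx, default_tokenizer)
    empty <- rep(list(character(0)), length(pm))
    new_corpus(pm, si, tx, tok, lapply(tok, tolower), empty, empty, gold)
  })
}
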