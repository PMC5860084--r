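#' Read MEDLINE/PubMed XML abstracts
#'
#' Parses `PubmedArticle` records into an abstract table, keeping the PubMed
#' identifier, title, abstract body (multiple `AbstractText` sections are
#' joined with a space), MeSH descriptor names and chemical-substance names.
#' Articles without abstract text are skipped with a warning.
#'
#' @param path path to a MEDLINE/PubMed XML file.
#' @return An object of class `hoc_abstracts`: a data frame with columns
#'   `pmid`, `title`, `body` and list-columns `mesh`, `chem`.
#' @export
read_medline_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  pmid <- character(0); title <- character(0); body <- character(0)
  mesh <- list(); chem <- list(); skipped <- 0L
  for (a in arts) {
    id <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    txt <- trimws(paste(xml2::xml_text(abst), collapse = " "))
    if (!length(abst) || !nzchar(txt)) { skipped <- skipped + 1L; next }
    pmid <- c(pmid, id)
    title <- c(title, xml2::xml_text(
      xml2::xml_find_first(a, ".//Article/ArticleTitle")))
    body <- c(body, txt)
    mesh[[length(mesh) + 1L]] <- xml2::xml_text(
      xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    chem[[length(chem) + 1L]] <- xml2::xml_text(
      xml2::xml_find_all(a, ".//ChemicalList/Chemical/NameOfSubstance"))
  }
  if (skipped > 0L)
    warning(skipped, " article(s) without abstract text skipped", call. = FALSE)
  out <- data.frame(pmid = pmid, title = title, body = body,
                    stringsAsFactors = FALSE)
  out$mesh <- mesh
  out$chem <- chem
  class(out) <- c("hoc_abstracts", "data.frame")
  out
}

#' Write abstracts as MEDLINE-like XML
#'
#' Inverse of [read_medline_xml()] for the fields this package consumes; used
#' by the synthetic-corpus generator to exercise the XML pathway.
#'
#' @param abstracts an `hoc_abstracts` data frame.
#' @param path output file path.
#' @export
write_medline_xml <- function(abstracts, path) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(abstracts))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", abstracts$pmid[i])
    article <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(article, "ArticleTitle", abstracts$title[i])
    abst <- xml2::xml_add_child(article, "Abstract")
    xml2::xml_add_child(abst, "AbstractText", abstracts$body[i])
    ml <- abstracts$mesh[[i]]
    if (length(ml)) {
      mhl <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (m in ml) {
        mh <- xml2::xml_add_child(mhl, "MeshHeading")
        xml2::xml_add_child(mh, "DescriptorName", m)
      }
    }
    cl <- abstracts$chem[[i]]
    if (length(cl)) {
      chl <- xml2::xml_add_child(cit, "ChemicalList")
      for (ch in cl) {
        che <- xml2::xml_add_child(chl, "Chemical")
        xml2::xml_add_child(che, "NameOfSubstance", ch)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Construct a sentence corpus from vectors
#'
#' The conversion hook for annotated corpora in other layouts: parse the
#' foreign format however you like, then assemble an `hoc_corpus` from
#' parallel vectors. Tokens and lemmas are derived from `text` when not
#' supplied.
#'
#' @param pmid,text character vectors (one element per sentence).
#' @param gold list of taxonomy-code character vectors, or `NULL`.
#' @param sent_index 0-based sentence positions; default numbers sentences
#'   consecutively within each `pmid` run.
#' @param mesh,chem optional metadata list-columns.
#' @param tokens,lemmas optional precomputed token/lemma lists.
#' @param tokenizer,lemmatizer used when `tokens`/`lemmas` are absent.
#' @return An `hoc_corpus`.
#' @export
as_corpus <- function(pmid, text, gold = NULL, sent_index = NULL,
                      mesh = NULL, chem = NULL, tokens = NULL, lemmas = NULL,
                      tokenizer = default_tokenizer,
                      lemmatizer = default_lemmatizer) {
  n <- length(text)
  stopifnot(length(pmid) == n)
  if (is.null(tokens)) tokens <- lapply(text, tokenizer)
  if (is.null(lemmas)) lemmas <- lapply(tokens, lemmatizer)
  if (is.null(sent_index)) {
    runs <- rle(pmid)$lengths
    sent_index <- unlist(lapply(runs, seq_len)) - 1L
  }
  empty <- rep(list(character(0)), n)
  new_corpus(pmid, sent_index, text, tokens, lemmas,
             mesh = if (is.null(mesh)) empty else mesh,
             chem = if (is.null(chem)) empty else chem,
             gold = if (is.null(gold)) empty else gold)
}

new_corpus <- function(pmid, sent_index, text, tokens, lemmas, mesh, chem,
                       gold, pred = NULL) {
  out <- data.frame(pmid = pmid, sent_index = as.integer(sent_index),
                    text = text, stringsAsFactors = FALSE)
  out$tokens <- tokens; out$lemmas <- lemmas
  out$mesh <- mesh; out$chem <- chem
  out$gold <- gold
  out$pred <- if (is.null(pred)) rep(list(character(0)), nrow(out)) else pred
  class(out) <- c("hoc_corpus", "data.frame")
  out
}

#' Split abstracts into a sentence corpus
#'
#' Segments each abstract body into sentences, tokenizes and lemmatizes them,
#' and copies the abstract's MeSH/chemical metadata onto every sentence (the
#' metadata is attached to abstracts, not sentences, but is informative for
#' sentence classification).
#'
#' @param abstracts an `hoc_abstracts` data frame.
#' @param segmenter,tokenizer,lemmatizer pluggable text functions; see
#'   [default_segmenter()].
#' @return An `hoc_corpus`: one row per sentence with columns `pmid`,
#'   `sent_index` (0-based), `text`, and list-columns `tokens`, `lemmas`,
#'   `mesh`, `chem`, `gold`, `pred`.
#' @export
split_sentences <- function(abstracts, segmenter = default_segmenter,
                            tokenizer = default_tokenizer,
                            lemmatizer = default_lemmatizer) {
  pm <- character(0); si <- integer(0); tx <- character(0)
  tok <- list(); lem <- list(); me <- list(); ch <- list()
  for (i in seq_len(nrow(abstracts))) {
    sents <- segmenter(abstracts$body[i])
    if (!length(sents)) {
      warning("abstract ", abstracts$pmid[i], " has no sentences",
              call. = FALSE)
      next
    }
    for (j in seq_along(sents)) {
      pm <- c(pm, abstracts$pmid[i]); si <- c(si, j - 1L)
      tx <- c(tx, sents[j])
      t <- tokenizer(sents[j])
      tok[[length(tok) + 1L]] <- t
      lem[[length(lem) + 1L]] <- lemmatizer(t)
      me[[length(me) + 1L]] <- abstracts$mesh[[i]]
      ch[[length(ch) + 1L]] <- abstracts$chem[[i]]
    }
  }
  new_corpus(pm, si, tx, tok, lem, me, ch,
             gold = rep(list(character(0)), length(pm)))
}

#' Read / write the annotated-corpus TSV
#'
#' Dialect: UTF-8, LF line endings, header
#' `pmid<TAB>sent_index<TAB>labels<TAB>text`; `labels` is a pipe-separated
#' list of taxonomy codes (or unambiguous node names), empty for unlabeled
#' sentences. Gold labels are stored exactly as annotated; ancestor (hypernym)
#' closure is applied at training time, not at read time.
#'
#' @param path file path.
#' @param taxonomy an `hoc_taxonomy` used to validate label tokens.
#' @param tokenizer,lemmatizer pluggable text functions.
#' @return `read_annotated_corpus`: an `hoc_corpus` (metadata columns empty;
#'   the TSV carries none).
#' @export
read_annotated_corpus <- function(path, taxonomy,
                                  tokenizer = default_tokenizer,
                                  lemmatizer = default_lemmatizer) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !identical(lines[1], "pmid\tsent_index\tlabels\ttext"))
    stop("not an annotated-corpus TSV (bad header): ", path, call. = FALSE)
  lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  pm <- character(n); si <- integer(n); tx <- character(n)
  gold <- vector("list", n); tok <- vector("list", n); lem <- vector("list", n)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || length(f) > 4L)
      stop("line ", k + 1L, ": expected 4 tab-separated fields", call. = FALSE)
    if (length(f) == 3L) f <- c(f, "")
    pm[k] <- f[1]; si[k] <- as.integer(f[2]); tx[k] <- f[4]
    toks <- if (nzchar(f[3])) strsplit(f[3], "|", fixed = TRUE)[[1]] else character(0)
    gold[[k]] <- resolve_labels(toks, taxonomy, where = paste0("line ", k + 1L))
    t <- tokenizer(f[4])
    tok[[k]] <- t
    lem[[k]] <- lemmatizer(t)
  }
  empty <- rep(list(character(0)), n)
  new_corpus(pm, si, tx, tok, lem, empty, empty, gold)
}

#' @param corpus an `hoc_corpus` to serialize.
#' @rdname read_annotated_corpus
#' @export
write_annotated_corpus <- function(corpus, path) {
  labs <- vapply(corpus$gold, paste, character(1), collapse = "|")
  lines <- c("pmid\tsent_index\tlabels\ttext",
             paste(corpus$pmid, corpus$sent_index, labs, corpus$text,
                   sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Attach abstract metadata to an annotated corpus
#'
#' Joins MeSH/chemical metadata from an abstract table onto the sentences of
#' an annotated corpus by `pmid`.
#'
#' @param corpus an `hoc_corpus`.
#' @param abstracts an `hoc_abstracts`.
#' @return The corpus with `mesh`/`chem` filled in.
#' @export
attach_metadata <- function(corpus, abstracts) {
  idx <- match(corpus$pmid, abstracts$pmid)
  for (k in seq_len(nrow(corpus))) {
    if (!is.na(idx[k])) {
      corpus$mesh[[k]] <- abstracts$mesh[[idx[k]]]
      corpus$chem[[k]] <- abstracts$chem[[idx[k]]]
    }
  }
  corpus
}

#' Distribution of labels-per-sentence
#'
#' @param corpus an `hoc_corpus` with gold labels.
#' @return Named numeric vector: proportion of sentences carrying `k` gold
#'   labels, keyed by `k`; sums to 1.
#' @export
label_distribution <- function(corpus) {
  if (!nrow(corpus)) stop("empty corpus", call. = FALSE)
  counts <- table(lengths(corpus$gold))
  out <- as.numeric(counts) / nrow(corpus)
  names(out) <- names(counts)
  out
}

#' @export
print.hoc_corpus <- function(x, ...) {
  cat(sprintf("Sentence corpus: %d sentences from %d abstracts; %d labelled (%.1f%%)\n",
              nrow(x), length(unique(x$pmid)), sum(lengths(x$gold) > 0),
              100 * mean(lengths(x$gold) > 0)))
  invisible(x)
}
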