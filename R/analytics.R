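#' Match a query against sentence tokens
#'
#' Case-insensitive contiguous token-sequence (phrase) matching: the query is
#' tokenized with the same tokenizer as the sentences and must appear as an
#' adjacent token run. No stemming or synonym expansion is applied.
#'
#' @param corpus an `hoc_corpus`.
#' @param query non-empty query text.
#' @param tokenizer tokenizer applied to the query.
#' @return Integer vector of matching row indices into `corpus`.
#' @export
match_query <- function(corpus, query, tokenizer = default_tokenizer) {
  q <- tolower(tokenizer(query))
  if (!length(q)) stop("empty query", call. = FALSE)
  m <- length(q)
  hits <- vapply(corpus$tokens, function(toks) {
    toks <- tolower(toks)
    n <- length(toks)
    if (n < m) return(FALSE)
    if (m == 1L) return(q %in% toks)
    for (s in seq_len(n - m + 1L))
      if (all(toks[s:(s + m - 1L)] == q)) return(TRUE)
    FALSE
  }, logical(1))
  which(hits)
}

#' Sentence-level co-occurrence counts for one hallmark
#'
#' @param corpus an `hoc_corpus`.
#' @param matched integer indices of query-matching sentences (from
#'   [match_query()]).
#' @param code taxonomy node code.
#' @param labels which label column to count: predicted (`"pred"`, default;
#'   associations are computed over the classified collection) or gold.
#' @return List of counts `N`, `n_q`, `n_h`, `n_hq`.
#' @export
count_cooccurrence <- function(corpus, matched, code,
                               labels = c("pred", "gold")) {
  labels <- match.arg(labels)
  if (!nrow(corpus)) stop("empty sentence collection", call. = FALSE)
  has_h <- vapply(corpus[[labels]], function(g) code %in% g, logical(1))
  is_q <- seq_len(nrow(corpus)) %in% matched
  list(N = nrow(corpus), n_q = sum(is_q), n_h = sum(has_h),
       n_hq = sum(is_q & has_h))
}

#' Conditional probability of a hallmark given the query
#'
#' `P(h | q) = P(h, q) / P(q)`, estimated as `n_hq / n_q`.
#'
#' @param counts a count list from [count_cooccurrence()].
#' @return Numeric in `[0, 1]`, or `NA_real_` when the query matches nothing.
#' @export
cprob <- function(counts) {
  if (counts$n_q == 0) return(NA_real_)
  counts$n_hq / counts$n_q
}

#' Pointwise mutual information and its normalization
#'
#' `PMI = log P(h,q) / (P(h) P(q))` (natural log) and
#' `NPMI = PMI / (-log P(h,q))`, which lies in `[-1, 1]`. Undefined (NA)
#' when any of `n_hq`, `n_h`, `n_q` is zero; NPMI additionally undefined
#' when `P(h,q) = 1`.
#'
#' @param counts a count list from [count_cooccurrence()].
#' @return Named numeric vector `c(pmi = , npmi = )` (possibly `NA`).
#' @export
pmi_npmi <- function(counts) {
  if (counts$n_hq == 0 || counts$n_h == 0 || counts$n_q == 0)
    return(c(pmi = NA_real_, npmi = NA_real_))
  p_hq <- counts$n_hq / counts$N
  pmi <- log(p_hq / ((counts$n_h / counts$N) * (counts$n_q / counts$N)))
  npmi <- if (p_hq == 1) NA_real_ else pmi / (-log(p_hq))
  c(pmi = pmi, npmi = npmi)
}

#' Expected-frequency rule for 2x2 test selection
#'
#' Computes the four expected cell counts (row total x column total / N) and
#' routes the table to the Fisher exact test when any expected count is below
#' five, otherwise to the chi-squared test. A table with a zero marginal row
#' or column is degenerate: Fisher with p = 1.
#'
#' @param table a 2x2 matrix of non-negative counts with a positive total.
#' @return List: `test` (`"fisher"` or `"chi2"`), `expected` (2x2 matrix),
#'   `degenerate` (logical).
#' @export
choose_test <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0), sum(table) > 0)
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  test <- if (degenerate || any(expected < 5)) "fisher" else "chi2"
  list(test = test, expected = expected, degenerate = degenerate)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: with fixed margins, the p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (up to a relative tolerance of 1e-7 for
#' floating-point ties).
#'
#' @param table a 2x2 matrix of non-negative counts.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  m <- sum(table[1, ])        # row-1 total
  n <- sum(table[2, ])        # row-2 total
  k <- sum(table[, 1])        # column-1 total
  if (m + n == 0 || k == 0 || k == m + n ||
      m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' One degree of freedom, no continuity correction; intended for tables that
#' pass the expected-frequency rule.
#'
#' @param table a 2x2 matrix of counts.
#' @return List: `statistic`, `p`.
#' @export
chi2_test <- function(table) {
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Hallmark association profile of a query
#'
#' For every taxonomy node, counts sentence-level co-occurrence between the
#' query and the node's (predicted) label, and derives the conditional
#' probability, PMI and NPMI.
#'
#' @param corpus an `hoc_corpus` whose `pred` column holds predicted labels
#'   (or use `labels = "gold"`).
#' @param query query text.
#' @param taxonomy an `hoc_taxonomy`.
#' @param labels `"pred"` or `"gold"`.
#' @return An `hoc_association` data frame: one row per node with columns
#'   `code`, `name`, `n_q`, `n_h`, `n_hq`, `cprob`, `pmi`, `npmi`.
#' @export
hallmark_associations <- function(corpus, query, taxonomy = hoc_taxonomy(),
                                  labels = c("pred", "gold")) {
  labels <- match.arg(labels)
  matched <- match_query(corpus, query)
  rows <- lapply(taxonomy$code, function(code) {
    cc <- count_cooccurrence(corpus, matched, code, labels)
    pn <- pmi_npmi(cc)
    data.frame(code = code, name = taxonomy$name[match(code, taxonomy$code)],
               N = cc$N, n_q = cc$n_q, n_h = cc$n_h, n_hq = cc$n_hq,
               cprob = cprob(cc), pmi = pn[["pmi"]], npmi = pn[["npmi"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "query") <- query
  class(out) <- c("hoc_association", "data.frame")
  out
}

#' Compare the hallmark profiles of two queries
#'
#' Per node, builds the 2x2 contingency table of the two queries'
#' matched-sentence sets against hallmark presence/absence, applies the
#' expected-frequency rule to pick Fisher's exact or the chi-squared test,
#' and Bonferroni-corrects over the number of nodes tested. Sentences
#' matching both queries are counted in both rows and flagged.
#'
#' @param corpus an `hoc_corpus` with predicted labels.
#' @param query_a,query_b two query texts, each matching at least one
#'   sentence.
#' @param taxonomy an `hoc_taxonomy` (or a subset of its rows, e.g. the ten
#'   top-level hallmarks).
#' @param labels `"pred"` or `"gold"`.
#' @return An `hoc_comparison` data frame: per node the table cells
#'   (`a_with`, `a_without`, `b_with`, `b_without`), `test_used`, `p_raw`,
#'   `p_corrected = min(1, m p_raw)`; attribute `overlap` counts sentences
#'   matching both queries.
#' @export
compare_queries <- function(corpus, query_a, query_b,
                            taxonomy = hoc_taxonomy(),
                            labels = c("pred", "gold")) {
  labels <- match.arg(labels)
  ma <- match_query(corpus, query_a)
  mb <- match_query(corpus, query_b)
  if (!length(ma)) stop("query matches no sentence: ", query_a, call. = FALSE)
  if (!length(mb)) stop("query matches no sentence: ", query_b, call. = FALSE)
  m <- nrow(taxonomy)
  rows <- lapply(taxonomy$code, function(code) {
    has_h <- vapply(corpus[[labels]], function(g) code %in% g, logical(1))
    tab <- matrix(c(sum(has_h[ma]), sum(!has_h[ma]),
                    sum(has_h[mb]), sum(!has_h[mb])),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("with", "without")))
    sel <- choose_test(tab)
    p <- if (sel$degenerate) 1
         else if (sel$test == "fisher") fisher_exact(tab)
         else chi2_test(tab)$p
    data.frame(code = code, name = taxonomy$name[match(code, taxonomy$code)],
               a_with = tab[1, 1], a_without = tab[1, 2],
               b_with = tab[2, 1], b_without = tab[2, 2],
               test_used = sel$test, p_raw = p,
               p_corrected = min(1, m * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "queries") <- c(query_a, query_b)
  attr(out, "overlap") <- length(intersect(ma, mb))
  class(out) <- c("hoc_comparison", "data.frame")
  out
}

#' Read a prediction TSV into a sentence collection
#'
#' Rebuilds an `hoc_corpus` (with the `pred` column filled from the
#' `final_labels` field) from the output of [write_predictions()], for use
#' by the query-association functions.
#'
#' @param path prediction TSV path.
#' @param taxonomy an `hoc_taxonomy` validating the label codes.
#' @param tokenizer tokenizer applied to the stored sentence text.
#' @return An `hoc_corpus` with `pred` populated and `gold` empty.
#' @export
read_prediction_corpus <- function(path, taxonomy = hoc_taxonomy(),
                                   tokenizer = default_tokenizer) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  stopifnot(all(c("pmid", "sent_index", "text", "final_labels") %in% names(df)))
  pred <- lapply(df$final_labels, function(s)
    if (nzchar(s)) resolve_labels(strsplit(s, "|", fixed = TRUE)[[1]], taxonomy)
    else character(0))
  tok <- lapply(df$text, tokenizer)
  empty <- rep(list(character(0)), nrow(df))
  new_corpus(df$pmid, as.integer(df$sent_index), df$text, tok,
             lapply(tok, default_lemmatizer), empty, empty,
             gold = empty, pred = pred)
}

#' Write association / comparison results
#'
#' TSV plus JSON serializations mirroring the downloadable analytics data.
#'
#' @param x an `hoc_association` or `hoc_comparison`.
#' @param path output path without extension; writes `<path>.tsv` and
#'   `<path>.json`.
#' @export
write_analytics <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(df, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
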