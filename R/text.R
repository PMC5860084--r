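#' Default sentence segmenter
#'
#' Rule-based splitter on `.`, `!`, `?` followed by whitespace and an
#' upper-case letter, digit or opening bracket, with protection for common
#' scientific abbreviations (`i.e.`, `e.g.`, `et al.`, `Fig.`, `cf.`, `vs.`,
#' `approx.`, `ca.`, `No.`) and for periods inside decimal numbers. The
#' segmenter is pluggable everywhere it is used; the identity of the segmenter
#' is recorded in model artifacts.
#'
#' Documented behaviour on edge cases: an abbreviation such as `"i.e."` in
#' mid-sentence does not split; a sentence-final abbreviation followed by an
#' upper-case word does split.
#'
#' @param text a single character string.
#' @return Character vector of sentences (whitespace-trimmed, no empties).
#' @export
default_segmenter <- function(text) {
  if (!nzchar(trimws(text))) return(character(0))
  protected <- c("i\\.e\\.", "e\\.g\\.", "et al\\.", "etc\\.", "cf\\.",
                 "vs\\.", "ca\\.", "approx\\.", "Fig\\.", "fig\\.", "No\\.",
                 "Dr\\.", "St\\.")
  x <- text
  for (p in protected)
    x <- gsub(paste0("\\b", p), gsub("\\\\\\.", "․", p, fixed = FALSE), x)
  # keep decimal points intact
  x <- gsub("(\\d)\\.(\\d)", "\\1․\\2", x)
  parts <- strsplit(x, "(?<=[.!?])\\s+(?=[A-Z0-9(\\[])", perl = TRUE)[[1]]
  parts <- gsub("․", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Default tokenizer and lemmatizer
#'
#' The tokenizer splits on runs of characters outside `[A-Za-z0-9_-]` and
#' drops empty tokens. The default lemmatizer is a lower-casing identity map
#' with a small inflection stripper (plural `-s` on words of length >= 4 not
#' ending in `-ss`/`-us`/`-is`); a morphological lemmatizer can be plugged in
#' via the `lemmatizer` arguments of the corpus readers.
#'
#' @param text a single character string (one sentence).
#' @return `default_tokenizer`: character vector of tokens.
#' @export
default_tokenizer <- function(text) {
  toks <- strsplit(text, "[^A-Za-z0-9_-]+")[[1]]
  toks[nzchar(toks)]
}

#' @param tokens character vector of tokens.
#' @return `default_lemmatizer`: character vector of lemmas, same length.
#' @rdname default_tokenizer
#' @export
default_lemmatizer <- function(tokens) {
  lem <- tolower(tokens)
  strip <- nchar(lem) >= 4L & grepl("s$", lem) &
    !grepl("(ss|us|is)$", lem)
  lem[strip] <- sub("s$", "", lem[strip])
  lem
}

#' Shipped English stopword list
#'
#' A fixed, version-stamped function-word list used by the lemmatized
#' bag-of-words and semantic-distance features.
#'
#' @return Character vector of lower-case stopwords.
#' @export
hoc_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "hallmarker")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}
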