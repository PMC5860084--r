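#' The built-in Hallmarks-of-Cancer taxonomy
#'
#' Returns the two-level (depth at most three by dotted code) taxonomy of the
#' ten cancer hallmarks and their 27 process subclasses: 37 nodes in total.
#' Codes are dotted hierarchical identifiers (`"3"`, `"3.1"`, `"7.1.2"`); the
#' parent of a node is its code with the last component removed.
#'
#' Note on numbering: the published class listing assigns the prefix `2.1` to
#' two different subclasses of hallmark 2. To keep codes unique,
#' "By evading contact inhibition" is stored under code `"2.2"`; its
#' human-readable name is unchanged.
#'
#' @return An object of class `hoc_taxonomy`: a data frame with columns
#'   `code`, `name`, `parent` (`NA` for the ten roots) and `level`.
#' @examples
#' tax <- hoc_taxonomy()
#' nrow(tax)                      # 37
#' sum(is.na(tax$parent))         # 10 top-level hallmarks
#' taxonomy_ancestors(tax, "7.1.2")
#' @export
hoc_taxonomy <- function() {
  rows <- list(
    c("1", "Sustaining proliferative signalling"),
    c("1.1", "Cell cycle"),
    c("1.2", "Growth factors growth promoting signals"),
    c("1.2.1", "Downstream signalling"),
    c("1.3", "Receptors"),
    c("2", "Evading growth suppressors"),
    c("2.1", "By deregulating cell cycle checkpoints"),
    c("2.1.1", "Cell cycle"),
    c("2.2", "By evading contact inhibition"),
    c("3", "Resisting cell death"),
    c("3.1", "Apoptosis"),
    c("3.2", "Autophagy"),
    c("3.3", "Necrosis"),
    c("4", "Enabling replicative immortality"),
    c("4.1", "Immortalization"),
    c("4.2", "Senescence"),
    c("5", "Inducing angiogenesis"),
    c("5.1", "By deregulating angiogenesis"),
    c("5.1.1", "Angiogenic factors"),
    c("6", "Activating invasion and metastasis"),
    c("6.1", "Invasion"),
    c("6.2", "Metastasis"),
    c("7", "Genomic instability and mutation"),
    c("7.1", "DNA damage"),
    c("7.1.1", "Adducts"),
    c("7.1.2", "Strand breaks"),
    c("7.2", "DNA repair mechanisms"),
    c("7.3", "Mutation"),
    c("8", "Tumor promoting inflammation"),
    c("8.1", "Immune response"),
    c("8.2", "Inflammation"),
    c("8.2.2", "Oxidative stress"),
    c("9", "Cellular energetics"),
    c("9.1", "Glycolysis/Warburg effect"),
    c("10", "Avoiding immune destruction"),
    c("10.1", "Immune response"),
    c("10.2", "Immunosuppression")
  )
  code <- vapply(rows, `[`, character(1), 1L)
  name <- vapply(rows, `[`, character(1), 2L)
  new_taxonomy(code, name)
}

#' Construct a taxonomy from codes and names
#'
#' Parents and levels are derived from the dotted code structure.
#'
#' @param code character vector of dotted hierarchical codes.
#' @param name character vector of node names, same length as `code`.
#' @return An `hoc_taxonomy` data frame.
#' @export
new_taxonomy <- function(code, name) {
  stopifnot(length(code) == length(name))
  parent <- vapply(strsplit(code, ".", fixed = TRUE), function(p) {
    if (length(p) <= 1L) NA_character_ else paste(p[-length(p)], collapse = ".")
  }, character(1))
  level <- lengths(strsplit(code, ".", fixed = TRUE))
  out <- data.frame(code = code, name = name, parent = parent,
                    level = as.integer(level), stringsAsFactors = FALSE)
  class(out) <- c("hoc_taxonomy", "data.frame")
  out
}

#' @export
print.hoc_taxonomy <- function(x, ...) {
  cat(sprintf("Hallmark taxonomy: %d nodes (%d top-level)\n",
              nrow(x), sum(is.na(x$parent))))
  indent <- strrep("  ", x$level - 1L)
  cat(paste0(indent, x$code, " ", x$name, collapse = "\n"), "\n")
  invisible(x)
}

#' Ancestor chain of a taxonomy node
#'
#' @param taxonomy an `hoc_taxonomy`.
#' @param code a node code present in `taxonomy`.
#' @return Character vector of ancestor codes ordered from immediate parent to
#'   root; empty for top-level nodes.
#' @export
taxonomy_ancestors <- function(taxonomy, code) {
  if (!code %in% taxonomy$code)
    stop("unknown taxonomy code: ", code, call. = FALSE)
  out <- character(0)
  cur <- taxonomy$parent[match(code, taxonomy$code)]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- taxonomy$parent[match(cur, taxonomy$code)]
  }
  out
}

#' Validate taxonomy invariants
#'
#' Checks code uniqueness, that each node's level matches its number of dotted
#' components, and that every non-root's parent code is present (forest
#' structure; acyclicity is implied by the code-derived parent links).
#'
#' @param taxonomy an `hoc_taxonomy`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
taxonomy_validate <- function(taxonomy) {
  v <- character(0)
  dup <- unique(taxonomy$code[duplicated(taxonomy$code)])
  for (d in dup) v <- c(v, sprintf("duplicate code: %s", d))
  comp <- lengths(strsplit(taxonomy$code, ".", fixed = TRUE))
  bad <- which(comp != taxonomy$level)
  for (i in bad)
    v <- c(v, sprintf("level mismatch at %s: level %d but %d components",
                      taxonomy$code[i], taxonomy$level[i], comp[i]))
  nonroot <- which(!is.na(taxonomy$parent))
  for (i in nonroot) {
    if (!taxonomy$parent[i] %in% taxonomy$code)
      v <- c(v, sprintf("orphan node %s: parent %s missing",
                        taxonomy$code[i], taxonomy$parent[i]))
    expected <- sub("\\.[^.]+$", "", taxonomy$code[i])
    if (!identical(taxonomy$parent[i], expected))
      v <- c(v, sprintf("parent of %s is %s, expected %s",
                        taxonomy$code[i], taxonomy$parent[i], expected))
  }
  v
}

#' Read / write a taxonomy as TSV
#'
#' Layout: UTF-8, header `code<TAB>name<TAB>parent`, one node per line, empty
#' parent field for the roots. Allows variant taxonomies beyond the built-in
#' hallmark hierarchy.
#'
#' @param path file path.
#' @return `read_taxonomy_tsv`: an `hoc_taxonomy`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  stopifnot(all(c("code", "name", "parent") %in% names(df)))
  tax <- new_taxonomy(df$code, df$name)
  viol <- taxonomy_validate(tax)
  if (length(viol))
    stop("invalid taxonomy in ", path, ":\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  tax
}

#' @param taxonomy an `hoc_taxonomy` to serialize.
#' @rdname read_taxonomy_tsv
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  df <- data.frame(code = taxonomy$code, name = taxonomy$name,
                   parent = ifelse(is.na(taxonomy$parent), "", taxonomy$parent),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Map user-supplied label tokens (codes or names) onto codes.
# Names are matched case-insensitively; ambiguous names (two subclasses share
# the name "Cell cycle" / "Immune response") must be given as codes.
resolve_labels <- function(tokens, taxonomy, where = NULL) {
  if (!length(tokens)) return(character(0))
  out <- character(length(tokens))
  lower_names <- tolower(taxonomy$name)
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (tok %in% taxonomy$code) { out[k] <- tok; next }
    hit <- which(lower_names == tolower(tok))
    if (length(hit) == 1L) { out[k] <- taxonomy$code[hit]; next }
    msg <- if (length(hit) > 1L) "ambiguous label name" else "unknown label"
    stop(msg, ": '", tok, "'", if (!is.null(where)) paste0(" (", where, ")"),
         call. = FALSE)
  }
  out
}
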