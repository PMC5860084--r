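#' Hypernym closure of a gold label set
#'
#' Unions a label set with all ancestors of its members, so subclass
#' annotations count as positive evidence for their parent classes (e.g. an
#' apoptosis sentence is a positive example of resisting cell death).
#'
#' @param labels character vector of taxonomy codes.
#' @param taxonomy an `hoc_taxonomy`.
#' @return Sorted character vector of codes closed over ancestry.
#' @export
closure_labels <- function(labels, taxonomy) {
  if (!length(labels)) return(character(0))
  anc <- unlist(lapply(labels, taxonomy_ancestors, taxonomy = taxonomy),
                use.names = FALSE)
  sort(unique(c(labels, anc)))
}

#' Inverse-proportional class weights
#'
#' Balanced weighting `w_c = N / (2 n_c)` for the positive and negative
#' class, compensating the heavy negative skew of one-vs-rest training.
#'
#' @param n_pos,n_neg positive/negative example counts (both >= 1).
#' @return Named numeric vector `c(pos = , neg = )`.
#' @export
compute_class_weights <- function(n_pos, n_neg) {
  if (n_pos < 1L || n_neg < 1L)
    stop("empty class: n_pos=", n_pos, ", n_neg=", n_neg, call. = FALSE)
  n <- n_pos + n_neg
  c(pos = n / (2 * n_pos), neg = n / (2 * n_neg))
}

# L1-loss linear SVM via dual coordinate descent on sparse binary rows.
# X: dgCMatrix (n x d); y: logical; returns w (length d) and bias.
fit_linear_svm <- function(X, y, C, class_weights, seed = 1L,
                           max_epochs = 300L, tol = 1e-3) {
  Xa <- cbind(X, 1)                       # bias as constant column
  tX <- Matrix::t(Xa)                     # CSC of t(X) == CSR of X
  yy <- ifelse(y, 1, -1)
  cost <- C * ifelse(y, class_weights[["pos"]], class_weights[["neg"]])
  fit <- .dcd_svm(tX@p, tX@i, tX@x, nrow(X), ncol(Xa), yy, cost,
                  as.integer(max_epochs), tol, as.integer(seed))
  list(weights = fit$w[seq_len(ncol(X))], bias = fit$w[ncol(Xa)],
       epochs = fit$epochs)
}

#' Training control parameters
#'
#' @param min_count,max_count feature-selection occurrence thresholds;
#'   `max_count` may be a named per-kind vector. Defaults: minimum 5
#'   occurrences, maximum 500.
#' @param kinds enabled feature kinds (see [feature_config()]).
#' @param lexicon,tagger optional verb-class lexicon and entity tagger.
#' @param sd_bins semantic-distance discretization bins.
#' @param embedding_dim joint embedding dimension.
#' @param C fixed margin-violation cost used when `tune_C = FALSE`.
#' @param C_grid geometric grid searched by inner cross-validation.
#' @param tune_C whether to select `C` per node by inner CV.
#' @param inner_folds,outer_folds fold counts for inner tuning CV and outer
#'   evaluation CV (defaults 5 and 4: train on 75\% / test on 25\% outer,
#'   80\%/20\% inner).
#' @param min_positives smallest closed-positive sentence count for which a
#'   node classifier is trained.
#' @param seed master seed; all stage seeds derive from it.
#' @return A `hoc_control` list.
#' @export
hoc_control <- function(min_count = 5L, max_count = 500L,
                        kinds = FEATURE_KINDS, lexicon = NULL, tagger = NULL,
                        sd_bins = 10L, embedding_dim = 50L,
                        C = 1, C_grid = c(0.01, 0.1, 1, 10, 100),
                        tune_C = FALSE, inner_folds = 5L, outer_folds = 4L,
                        min_positives = 2L, seed = 42L) {
  structure(list(min_count = min_count, max_count = max_count, kinds = kinds,
                 lexicon = lexicon, tagger = tagger, sd_bins = sd_bins,
                 embedding_dim = embedding_dim, C = C, C_grid = C_grid,
                 tune_C = tune_C, inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 min_positives = as.integer(min_positives),
                 seed = as.integer(seed)),
            class = "hoc_control")
}

# Precompute the SD bin key of every sentence for every label at once.
# Returns an n x n_labels character matrix (NA when no in-vocab lemma).
sd_bin_matrix <- function(corpus, embedding, bins) {
  W <- embedding$word_vectors
  L <- embedding$label_vectors
  wn <- sqrt(rowSums(W^2)); ln <- sqrt(rowSums(L^2))
  ok <- wn > 0
  S <- (W[ok, , drop = FALSE] / wn[ok]) %*% t(L / pmax(ln, .Machine$double.eps))
  S[, ln == 0] <- NA_real_
  vocab <- rownames(W)[ok]
  out <- matrix(NA_character_, nrow(corpus), nrow(L),
                dimnames = list(NULL, rownames(L)))
  for (k in seq_len(nrow(corpus))) {
    inv <- match(unique(tolower(corpus$lemmas[[k]])), vocab)
    inv <- inv[!is.na(inv)]
    if (!length(inv)) next
    sims <- suppressWarnings(apply(S[inv, , drop = FALSE], 2, max))
    out[k, ] <- ifelse(is.finite(sims),
                       vapply(sims, function(s)
                         if (is.na(s)) NA_character_ else sd_bin(s, bins),
                         character(1)),
                       NA_character_)
  }
  out
}

# Shared per-corpus feature state: base keys (all kinds except SD) plus the
# SD bin matrix, from which per-node key lists are assembled cheaply.
corpus_features <- function(corpus, control, embedding) {
  base_kinds <- setdiff(control$kinds, "SD")
  cfg <- feature_config(kinds = base_kinds, lexicon = control$lexicon,
                        tagger = control$tagger, sd_bins = control$sd_bins)
  base <- sentence_keys(corpus, cfg)
  sdm <- NULL
  if ("SD" %in% control$kinds && !is.null(embedding))
    sdm <- sd_bin_matrix(corpus, embedding, control$sd_bins)
  list(base = base, sd = sdm, config = cfg)
}

node_keys <- function(feats, code) {
  if (is.null(feats$sd) || !code %in% colnames(feats$sd)) return(feats$base)
  bins <- feats$sd[, code]
  out <- feats$base
  has <- !is.na(bins)
  out[has] <- Map(c, out[has], paste0("SD:", bins[has]))
  out
}

#' Fit the hierarchical one-vs-rest hallmark classifier
#'
#' Trains, for every taxonomy node with enough positive examples, a linear
#' max-margin (SVM) classifier over the node's own selected feature space,
#' using hypernym-closed gold labels as the positive class and
#' inverse-proportional class weighting. All sentences participate in every
#' node's training (one-vs-rest over the entire corpus). With
#' `control$tune_C = TRUE` the cost parameter is selected per node by
#' abstract-grouped inner cross-validation over `control$C_grid`.
#'
#' @param corpus an `hoc_corpus` with gold labels.
#' @param taxonomy an `hoc_taxonomy`.
#' @param control an [hoc_control()].
#' @return An object of class `hoc_model` with components `taxonomy`,
#'   `spaces`, `classifiers`, `embedding`, `control`, `excluded` (nodes with
#'   too few positives) and a provenance `config` stamp.
#' @seealso [predict.hoc_model()], [nested_cv()]
#' @export
hoc_train <- function(corpus, taxonomy = hoc_taxonomy(),
                      control = hoc_control()) {
  stopifnot(inherits(corpus, "hoc_corpus"))
  closed <- lapply(corpus$gold, closure_labels, taxonomy = taxonomy)
  embedding <- NULL
  if ("SD" %in% control$kinds && any(lengths(closed) > 0L))
    embedding <- train_embedding(corpus, taxonomy,
                                 dimension = control$embedding_dim,
                                 seed = control$seed)
  feats <- corpus_features(corpus, control, embedding)
  spaces <- list(); classifiers <- list(); excluded <- character(0)
  pos_mat <- vapply(taxonomy$code, function(code)
    vapply(closed, function(g) code %in% g, logical(1)),
    logical(nrow(corpus)))
  if (is.null(dim(pos_mat))) pos_mat <- matrix(pos_mat, nrow = nrow(corpus))
  colnames(pos_mat) <- taxonomy$code
  base_counts <- table(unlist(feats$base, use.names = FALSE))
  for (code in taxonomy$code) {
    y <- pos_mat[, code]
    if (sum(y) < control$min_positives || sum(!y) < 1L) {
      excluded <- c(excluded, code)
      next
    }
    keys <- node_keys(feats, code)
    counts <- base_counts
    if (!is.null(feats$sd)) {
      bins <- feats$sd[, code]
      if (any(!is.na(bins)))
        counts <- c(counts, table(paste0("SD:", bins[!is.na(bins)])))
    }
    space <- select_features(corpus, code, taxonomy, feats$config,
                             min_count = control$min_count,
                             max_count = control$max_count, keys = keys,
                             positive_pmids = unique(corpus$pmid[y]),
                             key_counts = counts)
    X <- vectorize_corpus(corpus, space, feats$config, keys = keys)
    cw <- compute_class_weights(sum(y), sum(!y))
    C <- control$C
    if (control$tune_C && length(control$C_grid) > 1L)
      C <- tune_cost(X, y, corpus$pmid, cw, control)
    fit <- fit_linear_svm(X, y, C, cw, seed = control$seed)
    names(fit$weights) <- space$keys
    classifiers[[code]] <- list(code = code, weights = fit$weights,
                                bias = fit$bias, C = C, class_weights = cw,
                                n_pos = sum(y), n_neg = sum(!y))
    spaces[[code]] <- space
  }
  if (length(excluded))
    warning("nodes with too few positives not trained: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  model <- list(taxonomy = taxonomy, spaces = spaces,
                classifiers = classifiers, embedding = embedding,
                control = control, excluded = excluded,
                config = list(segmenter = "default_segmenter",
                              lemmatizer = "default_lemmatizer",
                              package_version =
                                as.character(utils::packageVersion("hallmarker")),
                              seed = control$seed))
  class(model) <- "hoc_model"
  model
}

# Inner CV over the C grid for one node; folds grouped by abstract.
# Selects the C with the best pooled F1 (ties -> smaller C).
tune_cost <- function(X, y, pmid, class_weights, control) {
  folds <- group_folds(pmid, control$inner_folds,
                       seed = control$seed + 1L)
  f1s <- vapply(control$C_grid, function(C) {
    tp <- fp <- fn <- 0
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      if (!any(y[tr]) || all(y[tr])) next
      fit <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], C, class_weights,
                            seed = control$seed)
      sc <- as.vector(X[!tr, , drop = FALSE] %*% fit$weights) + fit$bias
      pred <- sc > 0
      tp <- tp + sum(pred & y[!tr]); fp <- fp + sum(pred & !y[!tr])
      fn <- fn + sum(!pred & y[!tr])
    }
    if (tp + fp == 0 || tp + fn == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  control$C_grid[which.max(f1s)]
}

# Deterministic abstract-grouped fold assignment (balanced counts).
group_folds <- function(pmid, k, seed) {
  groups <- unique(pmid)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), length(groups)))
  fold_of[match(pmid, groups)]
}

#' Predict hallmark labels for new sentences
#'
#' Computes, per taxonomy node, the signed linear decision score and raw
#' binary label (score > 0), then resolves disagreements by the
#' parent-favoring top-down rule into a hierarchy-consistent final label set.
#'
#' @param object an `hoc_model`.
#' @param corpus an `hoc_corpus` (gold labels not required).
#' @param ... unused.
#' @return An `hoc_predictions` object: list with `pmid`, `sent_index`,
#'   `scores` (sentences x nodes), `raw` (logical matrix) and `final` (list
#'   of hierarchy-consistent code sets).
#' @export
predict.hoc_model <- function(object, corpus, ...) {
  stopifnot(inherits(corpus, "hoc_corpus"))
  feats <- corpus_features(corpus, object$control, object$embedding)
  codes <- object$taxonomy$code
  scores <- matrix(NA_real_, nrow(corpus), length(codes),
                   dimnames = list(NULL, codes))
  for (code in names(object$classifiers)) {
    clf <- object$classifiers[[code]]
    X <- vectorize_corpus(corpus, object$spaces[[code]], feats$config,
                          keys = node_keys(feats, code))
    scores[, code] <- as.vector(X %*% clf$weights) + clf$bias
  }
  raw <- !is.na(scores) & scores > 0
  final_mat <- postprocess(raw, object$taxonomy)
  final <- apply(final_mat, 1, function(r) codes[r], simplify = FALSE)
  out <- list(pmid = corpus$pmid, sent_index = corpus$sent_index,
              text = corpus$text, scores = scores, raw = raw, final = final)
  class(out) <- "hoc_predictions"
  out
}

#' Parent-favoring hierarchy post-processing
#'
#' Integrates the independent per-node binary decisions into a coherent
#' multi-label assignment: scanning top-down, a node predicted positive whose
#' parent is (after resolution) negative is suppressed. Parent-positive with
#' child-negative is not a disagreement (subclasses are not exhaustive). The
#' result always satisfies hierarchy consistency and the operation is
#' idempotent.
#'
#' @param raw logical matrix (sentences x node codes) of raw binary labels,
#'   or a single logical vector named by code.
#' @param taxonomy an `hoc_taxonomy`.
#' @return Object of the same shape with inconsistent positives removed.
#' @export
postprocess <- function(raw, taxonomy) {
  vec <- is.null(dim(raw))
  m <- if (vec) matrix(raw, nrow = 1, dimnames = list(NULL, names(raw))) else raw
  ord <- order(taxonomy$level)
  for (i in ord) {
    code <- taxonomy$code[i]
    parent <- taxonomy$parent[i]
    if (is.na(parent) || !code %in% colnames(m)) next
    if (parent %in% colnames(m))
      m[, code] <- m[, code] & m[, parent]
    else
      m[, code] <- FALSE
  }
  if (vec) stats::setNames(as.logical(m[1, ]), colnames(m)) else m
}

#' @export
print.hoc_model <- function(x, ...) {
  cat(sprintf("Hallmark sentence classifier: %d/%d node models trained\n",
              length(x$classifiers), nrow(x$taxonomy)))
  if (length(x$excluded))
    cat("  not trained (too few positives):",
        paste(x$excluded, collapse = ", "), "\n")
  cat(sprintf("  feature kinds: %s\n", paste(x$control$kinds, collapse = ", ")))
  if (!is.null(x$embedding))
    cat(sprintf("  embedding: %d words, dimension %d\n",
                nrow(x$embedding$word_vectors), x$embedding$dimension))
  invisible(x)
}

#' @export
summary.hoc_model <- function(object, ...) {
  df <- do.call(rbind, lapply(object$classifiers, function(clf)
    data.frame(code = clf$code, n_pos = clf$n_pos, n_neg = clf$n_neg,
               n_features = length(clf$weights), C = clf$C,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' @export
coef.hoc_model <- function(object, code = NULL, ...) {
  if (is.null(code))
    return(lapply(object$classifiers, function(clf)
      c(clf$weights, `(bias)` = clf$bias)))
  clf <- object$classifiers[[code]]
  if (is.null(clf)) stop("no classifier for node ", code, call. = FALSE)
  c(clf$weights, `(bias)` = clf$bias)
}

#' @export
print.hoc_predictions <- function(x, ...) {
  cat(sprintf("Predictions for %d sentences; %d (%.1f%%) assigned >=1 hallmark\n",
              length(x$final), sum(lengths(x$final) > 0),
              100 * mean(lengths(x$final) > 0)))
  invisible(x)
}

#' Convert predictions to a data frame / TSV
#'
#' TSV layout: `pmid`, `sent_index`, `text`, pipe-joined `final_labels` and
#' `raw_labels`, and comma-joined per-node `scores` (`code=value`). The text
#' column makes the file self-contained for the analytics layer.
#'
#' @param x an `hoc_predictions`.
#' @param ... unused.
#' @export
as.data.frame.hoc_predictions <- function(x, ...) {
  codes <- colnames(x$raw)
  data.frame(pmid = x$pmid, sent_index = x$sent_index, text = x$text,
             final_labels = vapply(x$final, paste, character(1), collapse = "|"),
             raw_labels = vapply(seq_len(nrow(x$raw)), function(i)
               paste(codes[x$raw[i, ]], collapse = "|"), character(1)),
             scores = vapply(seq_len(nrow(x$scores)), function(i)
               paste(sprintf("%s=%.6g", codes, x$scores[i, ]), collapse = ","),
               character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.hoc_predictions
#' @param path output file path.
#' @export
write_predictions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Persist / restore a trained model as a plain-text directory
#'
#' Layout: `taxonomy.tsv`, `config.json`, optional `embedding.json`, and one
#' `space_<code>.json` / `weights_<code>.json` pair per trained node.
#'
#' @param model an `hoc_model`.
#' @param dir directory path (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_taxonomy_tsv(model$taxonomy, file.path(dir, "taxonomy.tsv"))
  ctrl <- model$control
  ctrl$lexicon <- NULL; ctrl$tagger <- NULL   # resources are not serializable
  jsonlite::write_json(list(config = model$config, control = unclass(ctrl),
                            excluded = model$excluded,
                            has_embedding = !is.null(model$embedding),
                            has_lexicon = !is.null(model$control$lexicon),
                            has_tagger = !is.null(model$control$tagger)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$embedding))
    write_embedding(model$embedding, file.path(dir, "embedding.json"))
  for (code in names(model$classifiers)) {
    safe <- gsub(".", "_", code, fixed = TRUE)
    write_feature_space(model$spaces[[code]],
                        file.path(dir, paste0("space_", safe, ".json")))
    clf <- model$classifiers[[code]]
    jsonlite::write_json(list(code = code, weights = unname(clf$weights),
                              bias = clf$bias, C = clf$C,
                              class_weights = as.list(clf$class_weights),
                              n_pos = clf$n_pos, n_neg = clf$n_neg),
                         file.path(dir, paste0("weights_", safe, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_model
#' @param lexicon,tagger resources to re-attach (they are referenced, not
#'   serialized, in the artifact).
#' @export
load_model <- function(dir, lexicon = NULL, tagger = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  taxonomy <- read_taxonomy_tsv(file.path(dir, "taxonomy.tsv"))
  control <- do.call(hoc_control, c(meta$control[
    setdiff(names(meta$control), c("kinds", "C_grid"))],
    list(kinds = meta$control$kinds, C_grid = meta$control$C_grid,
         lexicon = lexicon, tagger = tagger)))
  embedding <- NULL
  if (isTRUE(meta$has_embedding))
    embedding <- read_embedding(file.path(dir, "embedding.json"))
  spaces <- list(); classifiers <- list()
  for (f in list.files(dir, pattern = "^space_.*\\.json$")) {
    space <- read_feature_space(file.path(dir, f))
    spaces[[space$code]] <- space
    wf <- jsonlite::read_json(file.path(dir, sub("^space_", "weights_", f)),
                              simplifyVector = TRUE)
    classifiers[[space$code]] <-
      list(code = wf$code,
           weights = stats::setNames(wf$weights, space$keys),
           bias = wf$bias, C = wf$C,
           class_weights = unlist(wf$class_weights),
           n_pos = wf$n_pos, n_neg = wf$n_neg)
  }
  model <- list(taxonomy = taxonomy, spaces = spaces,
                classifiers = classifiers, embedding = embedding,
                control = control,
                excluded = as.character(meta$excluded %||% character(0)),
                config = meta$config)
  class(model) <- "hoc_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
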