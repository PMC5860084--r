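#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/total`, `F1 = 2 p r / (p + r)`, reported in percent.
#' A ratio with zero denominator is reported as 0 and flagged.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return Named list: `precision`, `recall`, `f1`, `accuracy` (percent) and
#'   `undefined` (character vector naming flagged metrics).
#' @export
prf_accuracy <- function(tp, fp, tn, fn) {
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  p <- unname(ratio(tp, tp + fp, "precision"))
  r <- unname(ratio(tp, tp + fn, "recall"))
  acc <- unname(ratio(tp + tn, tp + fp + tn + fn, "accuracy"))
  f1 <- unname(ratio(2 * p * r, p + r, "f1"))
  list(precision = 100 * p, recall = 100 * r, f1 = 100 * f1,
       accuracy = 100 * acc, undefined = undefined)
}

#' Macro and micro averaged evaluation report
#'
#' Macro averages are unweighted means of per-node percent metrics; micro
#' metrics are recomputed from the pooled confusion counts.
#'
#' @param counts data frame with columns `code`, `tp`, `fp`, `tn`, `fn` (one
#'   row per node).
#' @param fold_plan optional list recording outer/inner fold counts and seed.
#' @param excluded optional character vector of excluded node codes.
#' @return An `hoc_eval` object: list with `per_node` (metrics per node),
#'   `macro`, `micro`, `fold_plan`, `excluded`.
#' @export
macro_micro <- function(counts, fold_plan = NULL, excluded = character(0)) {
  stopifnot(nrow(counts) >= 1L)
  per <- lapply(seq_len(nrow(counts)), function(i)
    prf_accuracy(counts$tp[i], counts$fp[i], counts$tn[i], counts$fn[i]))
  per_node <- cbind(counts,
                    precision = vapply(per, `[[`, numeric(1), "precision"),
                    recall = vapply(per, `[[`, numeric(1), "recall"),
                    f1 = vapply(per, `[[`, numeric(1), "f1"),
                    accuracy = vapply(per, `[[`, numeric(1), "accuracy"))
  macro <- c(precision = mean(per_node$precision), recall = mean(per_node$recall),
             f1 = mean(per_node$f1), accuracy = mean(per_node$accuracy))
  pooled <- prf_accuracy(sum(counts$tp), sum(counts$fp), sum(counts$tn),
                         sum(counts$fn))
  micro <- c(precision = pooled$precision, recall = pooled$recall,
             f1 = pooled$f1, accuracy = pooled$accuracy)
  out <- list(per_node = per_node, macro = macro, micro = micro,
              fold_plan = fold_plan, excluded = excluded)
  class(out) <- "hoc_eval"
  out
}

#' @export
print.hoc_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d nodes\n", nrow(x$per_node)))
  cat(sprintf("  macro: P %.1f  R %.1f  F1 %.1f  Acc %.1f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"],
              x$macro["accuracy"]))
  cat(sprintf("  micro: P %.1f  R %.1f  F1 %.1f  Acc %.1f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"],
              x$micro["accuracy"]))
  if (length(x$excluded))
    cat("  excluded nodes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per node (code, name, counts, percent metrics to one decimal)
#' plus macro-average and micro-average footer rows.
#'
#' @param eval an `hoc_eval`.
#' @param taxonomy an `hoc_taxonomy` supplying node names.
#' @param path output file path.
#' @export
write_eval_tsv <- function(eval, taxonomy, path) {
  pn <- eval$per_node
  df <- data.frame(code = pn$code,
                   name = taxonomy$name[match(pn$code, taxonomy$code)],
                   tp = pn$tp, fp = pn$fp, tn = pn$tn, fn = pn$fn,
                   precision = sprintf("%.1f", pn$precision),
                   recall = sprintf("%.1f", pn$recall),
                   f1 = sprintf("%.1f", pn$f1),
                   accuracy = sprintf("%.1f", pn$accuracy),
                   stringsAsFactors = FALSE)
  foot <- data.frame(code = c("macro", "micro"), name = "", tp = NA, fp = NA,
                     tn = NA, fn = NA,
                     precision = sprintf("%.1f", c(eval$macro["precision"],
                                                   eval$micro["precision"])),
                     recall = sprintf("%.1f", c(eval$macro["recall"],
                                                eval$micro["recall"])),
                     f1 = sprintf("%.1f", c(eval$macro["f1"], eval$micro["f1"])),
                     accuracy = sprintf("%.1f", c(eval$macro["accuracy"],
                                                  eval$micro["accuracy"])),
                     stringsAsFactors = FALSE)
  utils::write.table(rbind(df, foot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Nested cross-validated evaluation
#'
#' Outer K-fold cross-validation (default 4: train on 75\%, test on 25\%)
#' with abstract-grouped folds, wrapped around inner cross-validation
#' (default 5-fold, i.e. 80\%/20\% within the outer training portion) that
#' tunes the SVM cost per node. Outer-fold test predictions are pooled into
#' one report. Nodes with fewer closed-positive sentences or abstracts than
#' outer folds are excluded with a warning recorded in the report.
#'
#' @param corpus an `hoc_corpus` with gold labels.
#' @param taxonomy an `hoc_taxonomy`.
#' @param control an [hoc_control()]; `tune_C` is forced on unless the grid
#'   has a single point.
#' @return An `hoc_eval` report (see [macro_micro()]).
#' @export
nested_cv <- function(corpus, taxonomy = hoc_taxonomy(),
                      control = hoc_control(tune_C = TRUE)) {
  closed <- lapply(corpus$gold, closure_labels, taxonomy = taxonomy)
  k <- control$outer_folds
  pos_sent <- vapply(taxonomy$code, function(code)
    sum(vapply(closed, function(g) code %in% g, logical(1))), numeric(1))
  pos_abs <- vapply(taxonomy$code, function(code)
    length(unique(corpus$pmid[vapply(closed, function(g) code %in% g,
                                     logical(1))])), numeric(1))
  eligible <- taxonomy$code[pos_sent >= k & pos_abs >= k]
  excluded <- setdiff(taxonomy$code, eligible)
  if (length(excluded))
    warning("nodes excluded from nested CV (too few positives): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  folds <- group_folds(corpus$pmid, k, seed = control$seed)
  counts <- data.frame(code = eligible, tp = 0, fp = 0, tn = 0, fn = 0,
                       stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    train <- corpus[folds != f, ]; class(train) <- class(corpus)
    test <- corpus[folds == f, ]; class(test) <- class(corpus)
    model <- hoc_train(train, taxonomy, control)
    preds <- predict(model, test)
    gold_closed <- lapply(test$gold, closure_labels, taxonomy = taxonomy)
    for (i in seq_len(nrow(counts))) {
      code <- counts$code[i]
      truth <- vapply(gold_closed, function(g) code %in% g, logical(1))
      pred <- vapply(preds$final, function(g) code %in% g, logical(1))
      counts$tp[i] <- counts$tp[i] + sum(pred & truth)
      counts$fp[i] <- counts$fp[i] + sum(pred & !truth)
      counts$tn[i] <- counts$tn[i] + sum(!pred & !truth)
      counts$fn[i] <- counts$fn[i] + sum(!pred & truth)
    }
  }
  macro_micro(counts,
              fold_plan = list(outer = k, inner = control$inner_folds,
                               seed = control$seed),
              excluded = excluded)
}

#' Leave-one-out feature ablation
#'
#' Runs nested cross-validation once with the full feature set and once per
#' feature kind with that kind removed, under identical fold assignments
#' (same seed), and reports the macro-F1 drop attributable to each kind.
#'
#' @param corpus,taxonomy,control as in [nested_cv()].
#' @param kinds feature kinds to ablate (default: all enabled kinds).
#' @return A list with `full` (the full-set `hoc_eval`), `ablated` (named
#'   list of `hoc_eval`), and `deltas` (named numeric: full macro-F1 minus
#'   ablated macro-F1; positive means the kind helps).
#' @export
ablate_features <- function(corpus, taxonomy = hoc_taxonomy(),
                            control = hoc_control(tune_C = TRUE),
                            kinds = control$kinds) {
  full <- nested_cv(corpus, taxonomy, control)
  ablated <- list(); deltas <- numeric(0)
  for (kind in kinds) {
    ctrl <- control
    ctrl$kinds <- setdiff(control$kinds, kind)
    ev <- nested_cv(corpus, taxonomy, ctrl)
    ablated[[kind]] <- ev
    deltas[kind] <- unname(full$macro["f1"] - ev$macro["f1"])
  }
  list(full = full, ablated = ablated, deltas = deltas)
}

#' Cohen's kappa inter-annotator agreement
#'
#' Per-node binary kappa `(p_o - p_e) / (1 - p_e)` over the common sentence
#' inventory, averaged (unweighted) over the requested nodes. Degenerate
#' nodes — where either annotator is constant and chance agreement is 1 —
#' are excluded from the mean and reported.
#'
#' @param a,b lists of label sets (character vectors of codes), one element
#'   per sentence, same length and order for both annotators.
#' @param nodes node codes over which to compute agreement.
#' @return List: `kappa` (mean over non-degenerate nodes), `per_node` (named
#'   numeric, `NA` for degenerate nodes), `degenerate` (codes excluded).
#' @export
cohen_kappa <- function(a, b, nodes) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  n <- length(a)
  per <- vapply(nodes, function(code) {
    xa <- vapply(a, function(g) code %in% g, logical(1))
    xb <- vapply(b, function(g) code %in% g, logical(1))
    po <- mean(xa == xb)
    pe <- mean(xa) * mean(xb) + (1 - mean(xa)) * (1 - mean(xb))
    if (pe >= 1) return(NA_real_)
    (po - pe) / (1 - pe)
  }, numeric(1))
  degenerate <- nodes[is.na(per)]
  list(kappa = mean(per, na.rm = TRUE), per_node = per,
       degenerate = degenerate)
}
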