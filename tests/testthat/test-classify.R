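test_that("hypernym closure adds every ancestor", {
  tax <- hoc_taxonomy()
  expect_setequal(closure_labels("3.1", tax), c("3", "3.1"))
  expect_equal(closure_labels(character(0), tax), character(0))
  expect_setequal(closure_labels("7.1.2", tax), c("7", "7.1", "7.1.2"))
  expect_setequal(closure_labels(c("3.1", "9.1"), tax),
                  c("3", "3.1", "9", "9.1"))
})

test_that("inverse-proportional class weights follow N/(2 n_c)", {
  expect_equal(compute_class_weights(10, 90), c(pos = 5, neg = 100 / 180),
               tolerance = 1e-4)
  expect_equal(compute_class_weights(50, 50), c(pos = 1, neg = 1))
  w <- compute_class_weights(1, 999)
  expect_equal(w[["pos"]], 500)
  expect_equal(w[["neg"]], 0.5005, tolerance = 1e-3)
  expect_error(compute_class_weights(0, 10), "empty class")
})

test_that("the dual coordinate-descent solver agrees with libsvm", {
  skip_if_not_installed("e1071")
  set.seed(77)
  n <- 200; d <- 30
  X <- Matrix::Matrix(matrix(rbinom(n * d, 1, 0.15), n, d), sparse = TRUE)
  y <- as.vector(X[, 1] + X[, 2] + X[, 3]) >= 2
  y[1:5] <- !y[1:5]                       # a few label flips: soft margin case
  cw <- compute_class_weights(sum(y), sum(!y))
  for (C in c(0.1, 1, 10)) {
    ours <- hallmarker:::fit_linear_svm(X, y, C, cw, max_epochs = 5000L,
                                        tol = 1e-6)
    ref <- e1071::svm(as.matrix(X), factor(ifelse(y, "pos", "neg"),
                                           levels = c("pos", "neg")),
                      kernel = "linear", cost = C, scale = FALSE,
                      class.weights = cw)
    w_ref <- drop(crossprod(ref$coefs, ref$SV))
    b_ref <- -ref$rho
    # orient the reference hyperplane toward the positive class
    sc <- as.vector(as.matrix(X) %*% w_ref) + b_ref
    if (mean(sc[y]) < mean(sc[!y])) { w_ref <- -w_ref; b_ref <- -b_ref }
    cos <- sum(ours$weights * w_ref) /
      sqrt(sum(ours$weights^2) * sum(w_ref^2))
    expect_gt(cos, 0.98)
    pred_ours <- (as.vector(X %*% ours$weights) + ours$bias) > 0
    pred_ref <- (as.vector(as.matrix(X) %*% w_ref) + b_ref) > 0
    expect_gte(mean(pred_ours == pred_ref), 0.97)
  }
})

test_that("training on a separable corpus reaches perfect training F1", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 21)
  model <- hoc_train(corpus, tax, hoc_control(seed = 21))
  expect_length(model$classifiers, 37L)
  expect_length(model$spaces, 37L)
  preds <- predict(model, corpus)
  gold <- lapply(corpus$gold, closure_labels, taxonomy = tax)
  for (code in tax$code) {
    cc <- node_confusion(preds, gold, code)
    expect_equal(prf_accuracy(cc["tp"], cc["fp"], cc["tn"], cc["fn"])$f1, 100)
  }
})

test_that("label-shuffled training collapses held-out F1 to chance", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 22)
  shuf <- corpus
  set.seed(22)
  shuf$gold <- sample(shuf$gold)
  train_idx <- shuf$pmid %in% unique(shuf$pmid)[1:70]
  train <- shuf[train_idx, ]; class(train) <- class(shuf)
  test <- shuf[!train_idx, ]; class(test) <- class(shuf)
  model <- suppressWarnings(hoc_train(train, tax,
                                      hoc_control(seed = 22, min_count = 3L)))
  preds <- predict(model, test)
  gold <- lapply(test$gold, closure_labels, taxonomy = tax)
  f1s <- vapply(names(model$classifiers), function(code) {
    cc <- node_confusion(preds, gold, code)
    prf_accuracy(cc["tp"], cc["fp"], cc["tn"], cc["fn"])$f1
  }, numeric(1))
  expect_lt(mean(f1s), 35)      # far below the separable-signal ceiling of 100
})

test_that("training and prediction are deterministic given the seed", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 4)
  held <- generate_separable_corpus(tax, n = 370, seed = 5)
  m1 <- hoc_train(corpus, tax, hoc_control(seed = 9))
  m2 <- hoc_train(corpus, tax, hoc_control(seed = 9))
  p1 <- predict(m1, held); p2 <- predict(m2, held)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$final, p2$final)
})

test_that("a sentence with no indexed feature is decided by the bias alone", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 13)
  model <- hoc_train(corpus, tax, hoc_control(seed = 13))
  alien <- make_corpus("Z", "qqq zzz vvv")
  p <- predict(model, alien)
  for (code in names(model$classifiers))
    expect_equal(unname(p$scores[1, code]), model$classifiers[[code]]$bias,
                 tolerance = 1e-9)
})

test_that("parent-favoring post-processing yields consistent, idempotent sets", {
  tax <- hoc_taxonomy()
  raw <- c("3" = FALSE, "3.1" = TRUE)
  expect_false(any(postprocess(raw, tax)))
  raw2 <- c("3" = TRUE, "3.1" = TRUE)
  expect_equal(postprocess(raw2, tax), raw2)
  raw3 <- c("7.1.2" = TRUE, "7.1" = FALSE, "7" = TRUE)
  out3 <- postprocess(raw3, tax)
  expect_equal(names(out3)[out3], "7")
  # fuzz: consistency and idempotence over random raw matrices
  set.seed(55)
  m <- matrix(runif(200 * 37) < 0.3, 200, 37, dimnames = list(NULL, tax$code))
  out <- postprocess(m, tax)
  parent_of <- tax$parent[match(colnames(out), tax$code)]
  for (j in which(!is.na(parent_of)))
    expect_true(all(out[, parent_of[j]] >= out[, j]))
  expect_identical(postprocess(out, tax), out)
})

test_that("model bundles survive a save/load round trip", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 2)
  held <- generate_separable_corpus(tax, n = 370, seed = 3)
  model <- hoc_train(corpus, tax, hoc_control(seed = 2))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_equal(length(back$classifiers), length(model$classifiers))
  p1 <- predict(model, held)
  p2 <- predict(back, held)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-12)
  expect_identical(p1$final, p2$final)
})

test_that("feature-count floors from the control reach the feature spaces", {
  tax <- hoc_taxonomy()
  corpus <- generate_separable_corpus(tax, n = 370, seed = 8)
  model <- hoc_train(corpus, tax, hoc_control(seed = 8, min_count = 5L,
                                              kinds = c("LBOW", "NGRAM")))
  cfg <- feature_config(kinds = c("LBOW", "NGRAM"))
  counts <- table(unlist(sentence_keys(corpus, cfg), use.names = FALSE))
  for (code in names(model$spaces)) {
    ks <- model$spaces[[code]]$keys
    if (length(ks)) expect_gte(min(counts[ks]), 5L)
  }
})
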