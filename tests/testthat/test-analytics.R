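pred_corpus <- function() {
  # 100 sentences; "p53" in 10, hallmark 3 predicted on 20, overlap 10
  text <- c(rep("the p53 protein was induced", 10),
            rep("cells proliferated in culture", 90))
  corpus <- make_corpus(rep(sprintf("P%03d", 1:25), each = 4), text)
  corpus$pred <- c(rep(list("3"), 10), rep(list("3"), 10),
                   rep(list(character(0)), 80))
  corpus
}

test_that("query matching is case-insensitive phrase matching over tokens", {
  corpus <- make_corpus(c("a", "a", "b"),
                        c("The P53 protein", "cell cycle arrest",
                          "cycle of the cell"))
  expect_equal(match_query(corpus, "p53"), 1L)
  expect_equal(match_query(corpus, "cell cycle"), 2L)   # adjacency required
  expect_length(match_query(corpus, "granulocyte"), 0L)
  expect_error(match_query(corpus, "  "), "empty query")
})

test_that("co-occurrence counting matches a brute-force double loop", {
  corpus <- pred_corpus()
  cc <- count_cooccurrence(corpus, match_query(corpus, "p53"), "3")
  expect_equal(cc, list(N = 100L, n_q = 10L, n_h = 20L, n_hq = 10L))
  set.seed(41)
  rnd <- make_corpus(sprintf("R%03d", 1:50),
                     replicate(50, paste(sample(c("apple", "pear", "plum"),
                                                4, TRUE), collapse = " ")))
  rnd$pred <- lapply(1:50, function(i)
    if (runif(1) < 0.4) "5" else character(0))
  matched <- match_query(rnd, "apple")
  cc2 <- count_cooccurrence(rnd, matched, "5")
  brute <- c(0L, 0L)
  for (i in 1:50) {
    q <- "apple" %in% rnd$tokens[[i]]
    h <- "5" %in% rnd$pred[[i]]
    brute <- brute + c(q, q && h)
  }
  expect_equal(cc2$n_q, brute[1])
  expect_equal(cc2$n_hq, brute[2])
})

test_that("conditional probability handles its boundary cases", {
  expect_equal(cprob(list(N = 100, n_q = 10, n_h = 20, n_hq = 4)), 0.4)
  expect_equal(cprob(list(N = 100, n_q = 7, n_h = 20, n_hq = 7)), 1)
  expect_true(is.na(cprob(list(N = 100, n_q = 0, n_h = 20, n_hq = 0))))
})

test_that("PMI and NPMI match the closed-form definitions", {
  v <- pmi_npmi(list(N = 100, n_q = 10, n_h = 20, n_hq = 10))
  expect_equal(v[["pmi"]], log(5), tolerance = 1e-12)
  expect_equal(v[["npmi"]], log(5) / (-log(0.1)), tolerance = 1e-12)
  # independence
  ind <- pmi_npmi(list(N = 100, n_q = 20, n_h = 50, n_hq = 10))
  expect_equal(ind[["pmi"]], 0, tolerance = 1e-12)
  expect_equal(ind[["npmi"]], 0, tolerance = 1e-12)
  # perfect co-occurrence maximum
  pc <- pmi_npmi(list(N = 100, n_q = 15, n_h = 15, n_hq = 15))
  expect_equal(pc[["npmi"]], 1, tolerance = 1e-12)
  # undefined cases
  expect_true(all(is.na(pmi_npmi(list(N = 10, n_q = 0, n_h = 5, n_hq = 0)))))
  expect_true(is.na(pmi_npmi(list(N = 10, n_q = 10, n_h = 10,
                                  n_hq = 10))[["npmi"]]))
})

test_that("defined NPMI always stays inside [-1, 1]", {
  set.seed(61)
  for (i in 1:2000) {
    N <- sample(2:500, 1)
    n_q <- sample(0:N, 1); n_h <- sample(0:N, 1)
    n_hq <- sample(0:min(n_q, n_h), 1)
    v <- pmi_npmi(list(N = N, n_q = n_q, n_h = n_h, n_hq = n_hq))
    if (!is.na(v[["npmi"]])) {
      expect_gte(v[["npmi"]], -1 - 1e-12)
      expect_lte(v[["npmi"]], 1 + 1e-12)
    }
    # symmetry of PMI in h and q
    v2 <- pmi_npmi(list(N = N, n_q = n_h, n_h = n_q, n_hq = n_hq))
    expect_identical(v[["pmi"]], v2[["pmi"]])
  }
})

test_that("the expected-frequency rule routes tables correctly", {
  expect_equal(choose_test(matrix(c(1, 3, 4, 2), 2))$test, "fisher")
  expect_equal(choose_test(matrix(50, 2, 2))$test, "chi2")
  # boundary: expected exactly 5 is not below five
  expect_equal(choose_test(matrix(5, 2, 2))$test, "chi2")
  deg <- choose_test(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$test, "fisher")
})

test_that("Fisher's exact test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(5, 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  # independent enumeration oracle via explicit binomial coefficients
  enum_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    supp <- max(0, k - n):min(k, m)
    p <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
    sum(p[p <= p[supp == tab[1, 1]] * (1 + 1e-7)])
  }
  set.seed(71)
  for (i in 1:200) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), min(1, enum_oracle(tab)),
                 tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-7)
  }
})

test_that("the chi-squared test matches the hand-derived Pearson statistic", {
  prop <- matrix(c(20, 30, 40, 60), 2)      # perfectly proportional
  res <- chi2_test(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  tab <- matrix(c(30, 10, 10, 30), 2)
  res2 <- chi2_test(tab)
  expect_equal(res2$statistic, 20, tolerance = 1e-12)  # 4 cells of 10^2/20
  expect_equal(res2$p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(chi2_test(t(tab))$statistic, res2$statistic, tolerance = 1e-12)
})

test_that("association profiles report counts and metrics per node", {
  corpus <- pred_corpus()
  assoc <- hallmark_associations(corpus, "p53")
  expect_equal(nrow(assoc), 37L)
  r3 <- assoc[assoc$code == "3", ]
  expect_equal(r3$n_hq, 10)
  expect_equal(r3$cprob, 1)
  expect_equal(r3$pmi, log(5), tolerance = 1e-12)
  expect_true(all(is.na(assoc$npmi) | (assoc$npmi >= -1 & assoc$npmi <= 1)))
})

test_that("query comparison applies the test-selection rule and Bonferroni", {
  corpus <- pred_corpus()
  corpus$pred[91:100] <- rep(list("5"), 10)
  cmp <- compare_queries(corpus, "p53", "cells")
  expect_equal(nrow(cmp), 37L)
  expect_true(all(cmp$test_used %in% c("fisher", "chi2")))
  expect_equal(cmp$p_corrected, pmin(1, 37 * cmp$p_raw), tolerance = 1e-12)
  # swapping the queries leaves the p-values unchanged
  rev <- compare_queries(corpus, "cells", "p53")
  expect_equal(rev$p_raw, cmp$p_raw, tolerance = 1e-12)
  # identical match sets give p = 1 everywhere
  same <- compare_queries(corpus, "p53", "P53")
  expect_true(all(same$p_raw == 1))
  expect_error(compare_queries(corpus, "p53", "absentterm"), "matches no")
  # a constructed exclusive association reaches corrected significance
  big <- make_corpus(sprintf("B%03d", 1:300),
                     c(rep("drugx was given", 150),
                       rep("placebo was given", 150)))
  big$pred <- c(rep(list("3"), 140), rep(list(character(0)), 10),
                rep(list(character(0)), 150))
  sig <- compare_queries(big, "drugx", "placebo")
  expect_lt(sig$p_corrected[sig$code == "3"], 0.05)
})

test_that("prediction TSVs round-trip into the analytics layer", {
  tax <- hoc_taxonomy()
  corpus <- pred_corpus()
  preds <- list(pmid = corpus$pmid, sent_index = corpus$sent_index,
                text = corpus$text,
                scores = matrix(0.5, nrow(corpus), 37,
                                dimnames = list(NULL, tax$code)),
                raw = matrix(FALSE, nrow(corpus), 37,
                             dimnames = list(NULL, tax$code)),
                final = corpus$pred)
  class(preds) <- "hoc_predictions"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, f)
  back <- read_prediction_corpus(f, tax)
  expect_equal(nrow(back), 100L)
  expect_identical(back$pred, corpus$pred)
  assoc <- hallmark_associations(back, "p53")
  expect_equal(assoc$n_hq[assoc$code == "3"], 10)
})
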