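test_that("binary metrics reproduce worked confusion-matrix examples", {
  # best open-source sentence-level detector: 107 positives, 893 negatives,
  # FP = round(0.028 * 893) = 25, FN = round(0.065 * 107) = 7
  m <- binary_metrics(confusion_matrix(tp = 100, fp = 25, fn = 7, tn = 868))
  expect_equal(m$f1, 0.862, tolerance = 1e-3)
  expect_equal(m$accuracy, 0.968)
  expect_equal(m$fpr, 0.028, tolerance = 1e-3)
  expect_equal(m$fnr, 0.065, tolerance = 1e-2)

  # whole-comment chat classifier: FP = round(0.129 * 893) = 115,
  # FN = round(0.187 * 107) = 20
  m2 <- binary_metrics(confusion_matrix(tp = 87, fp = 115, fn = 20, tn = 778))
  expect_equal(m2$f1, 0.563, tolerance = 1e-3)
  expect_equal(m2$accuracy, 0.865)
})

test_that("zero-denominator rates report 0 with a degenerate flag", {
  m <- binary_metrics(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 0)
  expect_true("precision" %in% m$degenerate)
  expect_true("recall" %in% m$degenerate)
  expect_error(binary_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("rate identities hold on random confusion matrices", {
  withr::with_seed(5, {
    for (i in 1:50) {
      cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                             sample(1:50, 1), sample(1:50, 1))
      m <- binary_metrics(cm)
      expect_equal(m$tpr + m$fnr, 1)
      expect_equal(m$fpr + m$tnr, 1)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
  })
})

test_that("ROC handles separation, ties, and the 4-pair worked example", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  # pos {0.8, 0.4}, neg {0.6, 0.2}: 3 of 4 pairs concordant
  expect_equal(roc_curve(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_false(roc_curve(c(0.1, 0.9), c(1, 1))$defined)
})

test_that("ROC curves are anchored and monotone in x", {
  withr::with_seed(8, {
    sc <- runif(30)
    g <- rbinom(30, 1, 0.4)
    cu <- roc_curve(sc, g)
    expect_equal(unlist(cu$points[1, ]), c(x = 0, y = 0))
    expect_equal(unlist(cu$points[nrow(cu$points), ]), c(x = 1, y = 1))
    expect_true(all(diff(cu$points$x) >= 0))
  })
})

test_that("trapezoidal ROC AUC equals the pairwise-concordance oracle", {
  withr::with_seed(19, {
    for (i in 1:30) {
      n <- sample(5:200, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
      gold <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (sum(gold) == 0 || sum(gold) == n) next
      expect_equal(roc_curve(scores, gold)$auc, oracle_auc(scores, gold),
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    scores <- runif(80)
    gold <- rbinom(80, 1, 0.3)
    ref <- as.numeric(pROC::auc(pROC::roc(gold, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve(scores, gold)$auc, ref, tolerance = 1e-10)
  })
})

test_that("PR curve covers perfect, uninformative, and degenerate cases", {
  expect_equal(pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # single positive ranked first: precision 1 at recall 1
  one <- pr_curve(c(0.9, 0.2, 0.1), c(1, 0, 0))
  expect_equal(one$points$y[one$points$x == 1][1], 1)
  expect_false(pr_curve(c(0.4, 0.6), c(0, 0))$defined)
  # right endpoint sits at recall 1
  withr::with_seed(4, {
    cu <- pr_curve(runif(50), rbinom(50, 1, 0.3))
    expect_equal(max(cu$points$x), 1)
  })
})

test_that("uninformative scores give PR AUC near prevalence", {
  withr::with_seed(101, {
    n <- 20000L
    prev <- 0.15
    gold <- rbinom(n, 1, prev)
    scores <- runif(n)  # independent of labels
    expect_equal(pr_curve(scores, gold)$auc, prev, tolerance = 0.02)
  })
})

test_that("hamming loss counts differing membership cells", {
  gold <- tibble::tibble(comment_id = c("a", "b"),
                         categories = list("adverse_reactions",
                                           c("personal_choices",
                                             "indeterminate")))
  same <- gold
  expect_equal(hamming_loss(same, gold), 0)

  pred <- tibble::tibble(comment_id = c("a", "b"),
                         categories = list(character(),
                                           c("personal_choices",
                                             "indeterminate")))
  expect_equal(hamming_loss(pred, gold), 1 / 16)

  # full complement on every cell
  comp <- tibble::tibble(comment_id = gold$comment_id,
                         categories = lapply(gold$categories, function(s) {
                           setdiff(rootcause_categories(), s)
                         }))
  expect_equal(hamming_loss(comp, gold), 1)

  bad <- tibble::tibble(comment_id = c("a", "zz"),
                        categories = list("indeterminate", "indeterminate"))
  expect_error(hamming_loss(bad, gold), "mismatch")
})

test_that("hamming loss equals the mean per-class error rate", {
  withr::with_seed(77, {
    for (i in 1:10) {
      inst <- random_multilabel_instance(sample(10:60, 1))
      hl <- hamming_loss(inst$pred, inst$gold, inst$cats)
      pm <- member_matrix(inst$pred$categories, inst$cats)
      gm <- member_matrix(inst$gold$categories, inst$cats)
      per_class <- vapply(seq_along(inst$cats), function(j) {
        mean(pm[, j] != gm[, j])
      }, numeric(1))
      expect_equal(hl, mean(per_class))
    }
  })
})

test_that("Jaccard and subset accuracy follow set semantics", {
  gold <- tibble::tibble(comment_id = "a",
                         categories = list(c("personal_choices",
                                             "adverse_reactions")))
  pred <- tibble::tibble(comment_id = "a",
                         categories = list(c("adverse_reactions",
                                             "indeterminate")))
  js <- jaccard_and_subset(pred, gold)
  expect_equal(js$jaccard, 1 / 3)
  expect_equal(js$subset_accuracy, 0)

  all_match <- jaccard_and_subset(gold, gold)
  expect_equal(all_match$jaccard, 1)
  expect_equal(all_match$subset_accuracy, 1)

  # empty/empty counts as a perfect match
  empty <- tibble::tibble(comment_id = "a", categories = list(character()))
  expect_equal(jaccard_and_subset(empty, empty)$jaccard, 1)
})

test_that("subset accuracy never exceeds sample-averaged Jaccard", {
  withr::with_seed(55, {
    for (i in 1:15) {
      inst <- random_multilabel_instance(sample(5:50, 1))
      js <- jaccard_and_subset(inst$pred, inst$gold, inst$cats)
      expect_lte(js$subset_accuracy, js$jaccard + 1e-12)
    }
  })
})

test_that("multilabel averages collapse correctly in degenerate cases", {
  # one class only: micro = macro = weighted = the per-class value
  pred <- tibble::tibble(comment_id = as.character(1:4),
                         categories = list("k1", character(), "k1", "k1"))
  gold <- tibble::tibble(comment_id = as.character(1:4),
                         categories = list("k1", "k1", character(), "k1"))
  rep1 <- multilabel_report(pred, gold, categories = "k1")
  expect_equal(rep1$micro_f1, rep1$macro_f1)
  expect_equal(rep1$micro_f1, rep1$weighted_f1)
  expect_equal(rep1$micro_f1, rep1$per_class[[1]]$f1)

  # balanced supports: weighted equals macro
  pred2 <- tibble::tibble(comment_id = as.character(1:4),
                          categories = list("k1", "k2", c("k1", "k2"),
                                            character()))
  gold2 <- tibble::tibble(comment_id = as.character(1:4),
                          categories = list("k1", "k1", "k2", "k2"))
  rep2 <- multilabel_report(pred2, gold2, categories = c("k1", "k2"))
  expect_equal(rep2$weighted_f1, rep2$macro_f1)
})

test_that("micro/macro/weighted F1 match a brute-force pooling oracle", {
  withr::with_seed(91, {
    for (i in 1:10) {
      inst <- random_multilabel_instance(sample(20:200, 1))
      rep <- multilabel_report(inst$pred, inst$gold, categories = inst$cats)
      pm <- member_matrix(inst$pred$categories, inst$cats)
      gm <- member_matrix(inst$gold$categories, inst$cats)
      oracle <- oracle_multilabel_f1(pm, gm)
      expect_equal(rep$micro_f1, oracle$micro)
      expect_equal(rep$macro_f1, oracle$macro)
      expect_equal(rep$weighted_f1, oracle$weighted)
    }
  })
})

test_that("AUC fields are undefined without scores and defined with them", {
  pred <- tibble::tibble(comment_id = c("a", "b"),
                         categories = list("personal_choices",
                                           "adverse_reactions"))
  gold <- pred
  rep <- multilabel_report(pred, gold)
  expect_false(rep$auc_defined)
  expect_true(is.na(rep$micro_roc_auc))

  corpus <- generate_corpus(synthetic_config(80, noise = 0.2, seed = 41))
  sc <- matched_mock_scorer(corpus, noise = 0.2)
  pos <- corpus$comments[corpus$gold_binary$consensus == 1L, ]
  preds <- rootcause_corpus(pos, sc, "CS1", category_hypotheses(cutoff = 0.5))
  rep2 <- multilabel_report(preds, corpus$gold_rootcause)
  expect_true(rep2$auc_defined)
  expect_true(rep2$micro_roc_auc >= 0 && rep2$micro_roc_auc <= 1)
  expect_true(rep2$micro_pr_auc >= 0 && rep2$micro_pr_auc <= 1)
})

test_that("missing multilabel predictions are excluded with a count", {
  pred <- tibble::tibble(comment_id = c("a", "b", "c"),
                         categories = list("personal_choices",
                                           NA_character_,
                                           "adverse_reactions"))
  gold <- tibble::tibble(comment_id = c("a", "b", "c"),
                         categories = list("personal_choices",
                                           "indeterminate",
                                           "adverse_reactions"))
  rep <- multilabel_report(pred, gold)
  expect_equal(rep$excluded, 1L)
  expect_equal(rep$subset_accuracy, 1)
})

test_that("dataset summaries print prevalence at one decimal", {
  gold <- c(rep(1L, 107), rep(0L, 893))
  ds <- dataset_summary(gold)
  expect_equal(ds$percent[ds$class == "dde"], 10.7)
  expect_equal(ds$n[ds$class == "non_dde"], 893L)
  expect_equal(dataset_summary(rep(0L, 10))$percent, c(100, 0))
  expect_error(dataset_summary(integer()), "no gold")
})

test_that("root-cause frequency tables match planted counts", {
  gold <- tibble::tibble(
    comment_id = as.character(1:10),
    categories = c(rep(list("personal_choices"), 6),
                   rep(list(c("personal_choices", "adverse_reactions")), 1),
                   rep(list("treatment_success"), 3))
  )
  freq <- rootcause_frequency(gold)
  expect_equal(freq$n[freq$category == "personal_choices"], 7L)
  expect_equal(freq$percent[freq$category == "personal_choices"], 70)
  expect_equal(freq$percent[freq$category == "adverse_reactions"], 10)
})
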