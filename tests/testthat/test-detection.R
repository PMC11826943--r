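mock_fixed_scores <- function(score_map) {
  # nli plug-in: max mapped score over keys found in the premise, else 0
  nli_scorer(function(premise, hyp_text) {
    keys <- names(score_map)
    hit <- vapply(keys, grepl, logical(1), x = premise, fixed = TRUE)
    if (any(hit)) max(unlist(score_map[hit])) else 0
  })
}

test_that("CS1 takes the max sentence score and thresholds strictly", {
  cm <- list(id = "x", text = "One here. Two here. Three here.")
  sc <- mock_fixed_scores(list(One = 0.10, Two = 0.97, Three = 0.30))
  r <- classify_cs1(cm, sc, cutoff = 0.95)
  expect_equal(r$model_prediction, 0.97)
  expect_equal(r$label, 1L)
  expect_equal(sort(r$unit_scores[[1]]), c(0.10, 0.30, 0.97))

  # all scores at zero stay negative for any positive cutoff
  r0 <- classify_cs1(cm, mock_fixed_scores(list()), cutoff = 0.05)
  expect_equal(r0$label, 0L)

  # a prediction exactly at the cutoff is negative (strict >)
  tie <- classify_cs1(cm, mock_fixed_scores(list(Two = 0.95)), cutoff = 0.95)
  expect_equal(tie$label, 0L)
})

test_that("empty comments get prediction 0 and a non-DDE label", {
  r <- classify_cs1(list(id = "e", text = ""), mock_fixed_scores(list()),
                    cutoff = 0.5)
  expect_equal(r$model_prediction, 0)
  expect_equal(r$label, 0L)
  expect_length(r$unit_scores[[1]], 0L)
})

test_that("scorer failures carry the comment id", {
  boom <- nli_scorer(function(p, h) stop("backend down"))
  expect_error(classify_cs1(list(id = "c42", text = "a."), boom), "c42")
})

test_that("CS2 chunk scores including 0.994 beat a 0.95 cutoff", {
  sents <- c("first part here", "second part here")
  cm <- list(id = "y", text = paste0(paste(sents, collapse = ". "), "."))
  sc <- nli_scorer(function(p, h) if (grepl("second", p)) 0.994 else 0.1)
  r <- classify_cs2(cm, sc, cutoff = 0.95, spec = tokenizer_spec(4))
  expect_equal(r$model_prediction, 0.994)
  expect_equal(r$label, 1L)
})

test_that("a one-chunk comment under CS2 equals scoring the whole text once", {
  cm <- list(id = "z", text = "Short comment. Fits easily.")
  seen <- character()
  sc <- nli_scorer(function(p, h) { seen <<- c(seen, p); 0.4 })
  r <- classify_cs2(cm, sc, cutoff = 0.3, spec = tokenizer_spec(100))
  expect_length(r$unit_scores[[1]], 1L)
  expect_equal(seen, "Short comment. Fits easily.")
  expect_equal(r$label, 1L)
})

test_that("CS2 stays total when the budget is below every sentence", {
  cm <- list(id = "w", text = "alpha beta gamma delta. epsilon zeta eta theta.")
  sc <- nli_scorer(function(p, h) 0.2)
  r <- classify_cs2(cm, sc, cutoff = 0.1, spec = tokenizer_spec(2))
  expect_gt(length(r$unit_scores[[1]]), 2L)
  expect_equal(r$label, 1L)
})

test_that("CS3 parses 1/0 answers and records missing after retries", {
  cm <- list(id = "q", text = "whatever text")
  expect_equal(classify_cs3(cm, chat_scorer(function(p) "1"))$label, 1L)
  expect_equal(classify_cs3(cm, chat_scorer(function(p) "Answer: 0"))$label, 0L)

  calls <- 0L
  garbage <- chat_scorer(function(p) { calls <<- calls + 1L; "no idea" },
                         retries = 2L)
  r <- classify_cs3(cm, garbage)
  expect_true(is.na(r$label))
  expect_equal(calls, 3L)  # initial try + 2 retries

  # recovery on retry
  calls <- 0L
  flaky <- chat_scorer(function(p) {
    calls <<- calls + 1L
    if (calls < 2L) "hmm" else "1"
  }, retries = 2L)
  expect_equal(classify_cs3(cm, flaky)$label, 1L)
})

test_that("CS1 label equals the OR of per-sentence thresholded labels", {
  corpus <- generate_corpus(synthetic_config(150, noise = 0.2, seed = 13))
  sc <- matched_mock_scorer(corpus, noise = 0.2)
  h <- default_hypothesis()
  for (cutoff in c(0.05, 0.5, 0.95)) {
    for (i in sample(nrow(corpus$comments), 40)) {
      cm <- corpus$comments[i, ]
      r <- classify_cs1(cm, sc, h, cutoff)
      per_sentence <- vapply(split_sentences(cm$text)$text, function(s) {
        score_entailment(s, h, sc) > cutoff
      }, logical(1))
      expect_equal(r$label, as.integer(any(per_sentence)))
    }
  }
})

test_that("CS1 prediction is invariant under sentence reordering", {
  withr::with_seed(21, {
    corpus <- generate_corpus(synthetic_config(40, noise = 0, seed = 5))
    sc <- matched_mock_scorer(corpus)
    for (i in sample(nrow(corpus$comments), 10)) {
      cm <- corpus$comments[i, ]
      sents <- split_sentences(cm$text)$text
      shuffled <- list(id = cm$id,
                       text = paste(sample(sents), collapse = " "))
      expect_equal(classify_cs1(shuffled, sc)$model_prediction,
                   classify_cs1(cm, sc)$model_prediction)
    }
  })
})

test_that("cutoff sweep produces one strict-threshold matrix per grid value", {
  preds <- tibble::tibble(comment_id = c("a", "b"),
                          model_prediction = c(0.2, 0.8))
  gold <- tibble::tibble(comment_id = c("a", "b"), consensus = c(0L, 1L))
  sw <- sweep_cutoffs(preds, gold, grid = c(0.5, 0.9))
  expect_equal(unlist(sw[sw$cutoff == 0.5, c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  expect_equal(sw$fn[sw$cutoff == 0.9], 1L)

  expect_equal(nrow(sweep_cutoffs(preds, gold)), 19L)
  expect_equal(length(cutoff_grid()), 19L)

  bad_gold <- tibble::tibble(comment_id = c("a", "zz"), consensus = c(0L, 1L))
  expect_error(sweep_cutoffs(preds, bad_gold), "zz")
})

test_that("predicted positives, TPR and FPR fall as the cutoff rises", {
  corpus <- generate_corpus(synthetic_config(300, noise = 0.15, seed = 31))
  sc <- matched_mock_scorer(corpus, noise = 0.15)
  det <- detect_corpus(corpus$comments, sc, "CS1", cutoff = 0.5)
  sw <- sweep_cutoffs(det, corpus$gold_binary)
  tpr <- sw$tp / (sw$tp + sw$fn)
  fpr <- sw$fp / (sw$fp + sw$tn)
  expect_true(all(diff(sw$tp + sw$fp) <= 0))
  expect_true(all(diff(tpr) <= 0))
  expect_true(all(diff(fpr) <= 0))
})
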