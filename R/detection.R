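#' Default cutoff grid
#'
#' Thresholds 0.05, 0.10, ..., 0.95, generated from integer numerators over
#' 100 so grid values compare exactly.
#'
#' @return Ascending numeric vector of 19 thresholds.
#' @export
cutoff_grid <- function() {
  seq(5L, 95L, by = 5L) / 100
}

detection_result <- function(comment_id, strategy, unit_scores, cutoff,
                             model_prediction, label) {
  tibble::tibble(
    comment_id = comment_id,
    strategy = strategy,
    model_prediction = model_prediction,
    cutoff = cutoff,
    label = label,
    unit_scores = list(unit_scores)
  )
}

#' Classify one comment with CS1 (individual sentences)
#'
#' Each sentence is scored individually against the hypothesis; the model
#' prediction is the maximum sentence score, and the comment is labeled DDE
#' when that maximum strictly exceeds the cutoff. An empty comment has no
#' sentences; its prediction is defined as 0, so any positive cutoff yields
#' non-DDE.
#'
#' @param comment One-row comment tibble (or list with `id`, `text`).
#' @param scorer Scorer from [mock_scorer()] or [nli_scorer()].
#' @param hyp A [hypothesis()]; defaults to [default_hypothesis()].
#' @param cutoff Threshold in \[0, 1\]; strict `>` decides the label, so a
#'   prediction exactly at the cutoff is negative.
#' @return One-row tibble: `comment_id`, `strategy`, `model_prediction`,
#'   `cutoff`, `label`, list-column `unit_scores`.
#' @export
classify_cs1 <- function(comment, scorer, hyp = default_hypothesis(),
                         cutoff = 0.9) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  sentences <- split_sentences(comment$text)
  scores <- score_units(sentences$text, hyp, scorer, comment$id)
  pred <- if (length(scores) > 0L) max(scores) else 0
  detection_result(comment$id, "CS1", scores, cutoff, pred,
                   as.integer(pred > cutoff))
}

#' Classify one comment with CS2 (token-budget groups of sentences)
#'
#' Sentences are packed into chunks by [group_sentences()] under the
#' scorer's token budget; each chunk is scored as a single premise and the
#' maximum chunk score is compared to the cutoff, as in CS1.
#'
#' @inheritParams classify_cs1
#' @param spec A [tokenizer_spec()] carrying the scorer's token budget.
#' @return One-row tibble as in [classify_cs1()], `strategy = "CS2"`.
#' @export
classify_cs2 <- function(comment, scorer, hyp = default_hypothesis(),
                         cutoff = 0.9, spec = tokenizer_spec(256L)) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  sentences <- split_sentences(comment$text, spec)
  chunks <- group_sentences(sentences, spec)
  scores <- score_units(chunks$text, hyp, scorer, comment$id)
  pred <- if (length(scores) > 0L) max(scores) else 0
  detection_result(comment$id, "CS2", scores, cutoff, pred,
                   as.integer(pred > cutoff))
}

score_units <- function(texts, hyp, scorer, comment_id) {
  tryCatch(
    vapply(texts, score_entailment, numeric(1), hyp = hyp, scorer = scorer,
           USE.NAMES = FALSE),
    error = function(e) {
      stop("scorer failed on comment ", comment_id, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Classify one comment with CS3 (entire comment via chat model)
#'
#' The whole comment is passed to the chat backend at once with a prompt
#' requesting a bare 1/0 answer. Unparseable responses are retried per the
#' scorer's retry budget; a persistently unparseable comment gets a missing
#' (`NA`) label, which the evaluation layer excludes with an explicit count
#' rather than imputing.
#'
#' @param comment One-row comment tibble (or list with `id`, `text`).
#' @param scorer A [chat_scorer()].
#' @return One-row tibble as in [classify_cs1()]: `strategy = "CS3"`,
#'   `model_prediction` equal to the binary label (`NA` if missing),
#'   `cutoff` absent (`NA`), empty `unit_scores`.
#' @export
classify_cs3 <- function(comment, scorer) {
  stopifnot(inherits(scorer, "dde_scorer"))
  if (scorer$backend != "chat") {
    stop("CS3 requires a chat backend scorer", call. = FALSE)
  }
  ans <- chat_ask(scorer, build_binary_prompt(comment$text),
                  parse_binary_response)
  label <- if (is.null(ans)) NA_integer_ else as.integer(ans)
  detection_result(comment$id, "CS3", numeric(), NA_real_,
                   as.numeric(label), label)
}

#' Classify a whole corpus of comments
#'
#' Corpus-level driver over [classify_cs1()], [classify_cs2()], or
#' [classify_cs3()].
#'
#' @param comments Comment tibble (see [read_comments()]).
#' @param scorer Scorer matching the strategy (chat backend for CS3).
#' @param strategy `"CS1"`, `"CS2"`, or `"CS3"`.
#' @inheritParams classify_cs2
#' @return Tibble with one row per comment.
#' @export
detect_corpus <- function(comments, scorer, strategy = c("CS1", "CS2", "CS3"),
                          hyp = default_hypothesis(), cutoff = 0.9,
                          spec = tokenizer_spec(256L)) {
  strategy <- match.arg(strategy)
  rows <- lapply(seq_len(nrow(comments)), function(i) {
    cm <- comments[i, ]
    switch(strategy,
      CS1 = classify_cs1(cm, scorer, hyp, cutoff),
      CS2 = classify_cs2(cm, scorer, hyp, cutoff, spec),
      CS3 = classify_cs3(cm, scorer)
    )
  })
  dplyr::bind_rows(rows)
}

#' Sweep cutoffs over precomputed model predictions
#'
#' Scores are computed once and thresholded at every grid value with the
#' strict `>` rule, yielding one confusion matrix per cutoff.
#'
#' @param predictions Tibble with `comment_id` and `model_prediction`
#'   (e.g. from [detect_corpus()]).
#' @param gold Tibble with `comment_id` and `consensus` (0/1 gold labels).
#' @param grid Ascending thresholds; defaults to [cutoff_grid()].
#' @return Tibble with `cutoff`, `tp`, `fp`, `fn`, `tn`.
#' @export
sweep_cutoffs <- function(predictions, gold, grid = cutoff_grid()) {
  stopifnot(all(diff(grid) > 0), all(grid > 0), all(grid < 1))
  orphan_pred <- setdiff(predictions$comment_id, gold$comment_id)
  orphan_gold <- setdiff(gold$comment_id, predictions$comment_id)
  if (length(orphan_pred) + length(orphan_gold) > 0L) {
    stop("prediction/gold id mismatch; unmatched predictions: [",
         paste(orphan_pred, collapse = ", "), "], unmatched gold: [",
         paste(orphan_gold, collapse = ", "), "]", call. = FALSE)
  }
  j <- dplyr::inner_join(
    predictions[, c("comment_id", "model_prediction")],
    gold[, c("comment_id", "consensus")],
    by = "comment_id"
  )
  dplyr::bind_rows(lapply(grid, function(c) {
    lab <- as.integer(j$model_prediction > c)
    tibble::tibble(
      cutoff = c,
      tp = sum(lab == 1L & j$consensus == 1L),
      fp = sum(lab == 1L & j$consensus == 0L),
      fn = sum(lab == 0L & j$consensus == 1L),
      tn = sum(lab == 0L & j$consensus == 0L)
    )
  }))
}
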