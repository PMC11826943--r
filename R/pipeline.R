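#' @keywords internal
write_manifest <- function(out_dir, stage, params, counts) {
  manifest <- list(
    package = "ddetect",
    version = as.character(utils::packageVersion("ddetect")),
    stage = stage,
    params = params,
    counts = counts,
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a corpus and write it to disk
#'
#' Writes comments (JSONL), binary and root-cause gold (CSV), the matched
#' cue table (CSV), a lexicon, and a run manifest under one directory.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return The corpus, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(config)
  write_comments(corpus$comments, file.path(out_dir, "comments.jsonl"),
                 "jsonl")
  write_gold_binary(corpus$gold_binary,
                    file.path(out_dir, "gold_binary.csv"))
  write_gold_rootcause(corpus$gold_rootcause,
                       file.path(out_dir, "gold_rootcause.csv"))
  readr::write_csv(corpus$manifest$cue_table,
                   file.path(out_dir, "cue_table.csv"), progress = FALSE)
  writeLines(corpus$manifest$lexicon, file.path(out_dir, "lexicon.txt"))
  write_manifest(out_dir, "simulate",
                 corpus$manifest[setdiff(names(corpus$manifest), "cue_table")],
                 list(comments = nrow(corpus$comments),
                      positives = corpus$manifest$n_positive))
  invisible(corpus)
}

#' Apply the keyword prefilter to a comment file
#'
#' @param in_path,out_path Input/output comment files (JSONL).
#' @param lexicon_path Plain-text lexicon, one term per line.
#' @return Number of retained comments, invisibly.
#' @export
pipeline_filter <- function(in_path, lexicon_path, out_path) {
  comments <- read_comments(in_path, "jsonl")
  lexicon <- read_lexicon(lexicon_path)
  kept <- keyword_filter(comments, lexicon)
  write_comments(kept, out_path, "jsonl")
  write_manifest(dirname(out_path), "filter",
                 list(lexicon_terms = length(lexicon)),
                 list(in_comments = nrow(comments), kept = nrow(kept)))
  invisible(nrow(kept))
}

#' Run DDE detection over a comment file
#'
#' @param in_path Input comments (JSONL).
#' @param out_path Output predictions (JSONL: comment_id, strategy,
#'   model_prediction, cutoff, label, unit_scores).
#' @param scorer Scorer object.
#' @param strategy `"CS1"`, `"CS2"`, or `"CS3"`.
#' @param cutoff Threshold for CS1/CS2.
#' @param hyp Detection [hypothesis()].
#' @param spec [tokenizer_spec()] for CS2.
#' @return The predictions tibble, invisibly.
#' @export
pipeline_detect <- function(in_path, out_path, scorer,
                            strategy = c("CS1", "CS2", "CS3"), cutoff = 0.9,
                            hyp = default_hypothesis(),
                            spec = tokenizer_spec(256L)) {
  strategy <- match.arg(strategy)
  comments <- read_comments(in_path, "jsonl")
  preds <- detect_corpus(comments, scorer, strategy, hyp, cutoff, spec)
  lines <- vapply(seq_len(nrow(preds)), function(i) {
    jsonlite::toJSON(list(
      comment_id = preds$comment_id[i], strategy = preds$strategy[i],
      model_prediction = preds$model_prediction[i],
      cutoff = preds$cutoff[i], label = preds$label[i],
      unit_scores = preds$unit_scores[[i]]
    ), auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, out_path, useBytes = TRUE)
  write_manifest(dirname(out_path), "detect",
                 list(strategy = strategy, cutoff = cutoff,
                      hypothesis = hyp$text,
                      backend = scorer$backend,
                      seed = scorer$seed %||% NA),
                 list(comments = nrow(preds),
                      missing = sum(is.na(preds$label))))
  invisible(preds)
}

#' Read a detection predictions file
#'
#' @param path Predictions JSONL written by [pipeline_detect()].
#' @return Predictions tibble.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dplyr::bind_rows(lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(
      comment_id = rec$comment_id, strategy = rec$strategy,
      model_prediction = rec$model_prediction %||% NA_real_,
      cutoff = rec$cutoff %||% NA_real_,
      label = as.integer(rec$label %||% NA_integer_),
      unit_scores = list(as.numeric(rec$unit_scores))
    )
  }))
}

#' Run root-cause classification over a comment file
#'
#' @inheritParams pipeline_detect
#' @param hyps Category hypotheses from [category_hypotheses()].
#' @return The root-cause predictions tibble, invisibly.
#' @export
pipeline_rootcause <- function(in_path, out_path, scorer,
                               strategy = c("CS1", "CS2", "CS3"),
                               hyps = category_hypotheses(),
                               spec = tokenizer_spec(256L)) {
  strategy <- match.arg(strategy)
  comments <- read_comments(in_path, "jsonl")
  preds <- rootcause_corpus(comments, scorer, strategy, hyps, spec)
  lines <- vapply(seq_len(nrow(preds)), function(i) {
    jsonlite::toJSON(list(
      comment_id = preds$comment_id[i], strategy = preds$strategy[i],
      categories = preds$categories[[i]],
      per_category_scores = as.list(preds$per_category_scores[[i]])
    ), na = "null", auto_unbox = FALSE, digits = NA)
  }, character(1))
  writeLines(lines, out_path, useBytes = TRUE)
  n_missing <- sum(vapply(preds$categories, function(s) {
    length(s) == 1L && is.na(s)
  }, logical(1)))
  write_manifest(dirname(out_path), "rootcause",
                 list(strategy = strategy, backend = scorer$backend),
                 list(comments = nrow(preds), missing = n_missing))
  invisible(preds)
}

#' Sweep cutoffs over a predictions file
#'
#' @param pred_path Predictions JSONL (scores already computed).
#' @param gold_path Gold binary CSV.
#' @param out_path Output CSV of per-cutoff confusion matrices and rates.
#' @param grid Thresholds; defaults to [cutoff_grid()].
#' @return The sweep tibble, invisibly.
#' @export
pipeline_sweep <- function(pred_path, gold_path, out_path,
                           grid = cutoff_grid()) {
  preds <- read_predictions(pred_path)
  gold <- read_gold_binary(gold_path)
  sw <- sweep_cutoffs(preds, gold, grid)
  rates <- dplyr::bind_rows(lapply(seq_len(nrow(sw)), function(i) {
    m <- binary_metrics(confusion_matrix(sw$tp[i], sw$fp[i], sw$fn[i],
                                         sw$tn[i]))
    tibble::tibble(f1 = m$f1, accuracy = m$accuracy, tpr = m$tpr,
                   fpr = m$fpr)
  }))
  out <- dplyr::bind_cols(sw, rates)
  readr::write_csv(out, out_path, progress = FALSE)
  invisible(out)
}

#' Evaluate a predictions file against gold labels
#'
#' Writes a JSON metrics report: binary confusion rates plus the
#' excluded-count of missing predictions.
#'
#' @inheritParams pipeline_sweep
#' @param out_path Output JSON report.
#' @return The metrics list, invisibly.
#' @export
pipeline_evaluate <- function(pred_path, gold_path, out_path) {
  preds <- read_predictions(pred_path)
  gold <- read_gold_binary(gold_path)
  orphans <- setdiff(preds$comment_id, gold$comment_id)
  if (length(orphans) > 0L ||
      length(setdiff(gold$comment_id, preds$comment_id)) > 0L) {
    stop("prediction/gold id mismatch", call. = FALSE)
  }
  j <- dplyr::inner_join(preds[, c("comment_id", "label")],
                         gold[, c("comment_id", "consensus")],
                         by = "comment_id")
  m <- binary_metrics(confusion_from_labels(j$label, j$consensus))
  jsonlite::write_json(unclass(m), out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(m)
}
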