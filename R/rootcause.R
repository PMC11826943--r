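#' The closed root-cause taxonomy
#'
#' The eight categories a drug-discontinuation comment can be annotated
#' with: successful treatment completion; perceived inefficacy; adverse or
#' allergic reactions; accessibility problems (cost, prescriber, market);
#' personal choices (nonadherence without medical advice); other medical
#' reasons; indeterminate reasons; and non-discontinuation (the comment
#' turns out not to report stopping at all). The enumeration is closed:
#' predictions outside it are rejected.
#'
#' @return Character vector of the 8 category names, in canonical order.
#' @export
rootcause_categories <- function() {
  c("treatment_success", "treatment_inefficacy", "adverse_reactions",
    "accessibility_issues", "personal_choices", "alternative_medical_reasons",
    "indeterminate", "non_discontinuation")
}

#' Human-readable display names for the taxonomy
#' @return Named character vector mapping category to display name.
#' @export
rootcause_display_names <- function() {
  c(treatment_success = "Treatment success",
    treatment_inefficacy = "Treatment inefficacy",
    adverse_reactions = "Adverse reactions",
    accessibility_issues = "Accessibility issues",
    personal_choices = "Personal choices",
    alternative_medical_reasons = "Alternative medical reasons",
    indeterminate = "Indeterminate",
    non_discontinuation = "Nondiscontinuation")
}

#' Per-category hypotheses and cutoffs
#'
#' One entailment hypothesis and one cutoff per category. The default
#' hypothesis strings paraphrase the taxonomy definitions; every one is
#' overridable, and a single global cutoff applies unless a per-category
#' cutoff is given.
#'
#' @param cutoff Global default cutoff in \[0, 1\].
#' @param hypotheses Optional named character vector overriding hypothesis
#'   texts for some or all categories.
#' @param cutoffs Optional named numeric vector overriding cutoffs.
#' @return Tibble with `category`, `hypothesis`, `cutoff` covering all 8
#'   categories.
#' @export
category_hypotheses <- function(cutoff = 0.5, hypotheses = NULL,
                                cutoffs = NULL) {
  defaults <- c(
    treatment_success = "This person stopped a medication because the treatment succeeded or their health improved enough.",
    treatment_inefficacy = "This person stopped a medication because it was not working or they lost faith in it.",
    adverse_reactions = "This person stopped a medication because of side effects or an adverse reaction.",
    accessibility_issues = "This person stopped a medication because of cost, availability, or a prescriber decision.",
    personal_choices = "This person stopped a medication by personal choice without medical advice.",
    alternative_medical_reasons = "This person stopped a medication for another medical reason.",
    indeterminate = "This person stopped a medication for an unclear or unspecified reason.",
    non_discontinuation = "This person did not stop taking any medication."
  )
  if (!is.null(hypotheses)) {
    bad <- setdiff(names(hypotheses), rootcause_categories())
    if (length(bad) > 0L) stop("unknown categor(ies): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(hypotheses)] <- hypotheses
  }
  cuts <- stats::setNames(rep(cutoff, 8L), rootcause_categories())
  if (!is.null(cutoffs)) {
    bad <- setdiff(names(cutoffs), rootcause_categories())
    if (length(bad) > 0L) stop("unknown categor(ies): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    cuts[names(cutoffs)] <- cutoffs
  }
  stopifnot(all(cuts >= 0 & cuts <= 1))
  tibble::tibble(
    category = rootcause_categories(),
    hypothesis = unname(defaults[rootcause_categories()]),
    cutoff = unname(cuts[rootcause_categories()])
  )
}

rootcause_result <- function(comment_id, strategy, categories, scores) {
  tibble::tibble(
    comment_id = comment_id,
    strategy = strategy,
    categories = list(categories),
    per_category_scores = list(scores)
  )
}

# shared CS1/CS2 core: max score per category over text units, then
# per-category thresholding with strict >
rootcause_over_units <- function(comment_id, units, scorer, hyps, strategy) {
  scores <- vapply(seq_len(nrow(hyps)), function(k) {
    h <- hypothesis(hyps$hypothesis[k], label = hyps$category[k])
    s <- score_units(units, h, scorer, comment_id)
    if (length(s) > 0L) max(s) else 0
  }, numeric(1))
  names(scores) <- hyps$category
  cats <- hyps$category[scores > hyps$cutoff]
  rootcause_result(comment_id, strategy, cats, scores)
}

#' Root causes via CS1 (per-sentence union)
#'
#' Each sentence is scored against every category hypothesis; a category's
#' comment-level score is the maximum over sentences, so a category is
#' present exactly when some sentence exceeds its cutoff — union semantics
#' over sentences by the max construction. Multiple categories may apply.
#'
#' @param comment One-row comment tibble (or list with `id`, `text`).
#' @param scorer Scorer from [mock_scorer()] or [nli_scorer()].
#' @param hyps Category hypotheses from [category_hypotheses()].
#' @return One-row tibble: `comment_id`, `strategy`, list-columns
#'   `categories` and `per_category_scores` (named numeric, all 8).
#' @export
classify_rootcause_cs1 <- function(comment, scorer,
                                   hyps = category_hypotheses()) {
  sentences <- split_sentences(comment$text)
  rootcause_over_units(comment$id, sentences$text, scorer, hyps, "CS1")
}

#' Root causes via CS2 (per-chunk)
#'
#' As [classify_rootcause_cs1()] but the scored units are token-budget
#' chunks of consecutive sentences, preserving cross-sentence context.
#'
#' @inheritParams classify_rootcause_cs1
#' @param spec A [tokenizer_spec()] carrying the token budget.
#' @export
classify_rootcause_cs2 <- function(comment, scorer,
                                   hyps = category_hypotheses(),
                                   spec = tokenizer_spec(256L)) {
  sentences <- split_sentences(comment$text, spec)
  chunks <- group_sentences(sentences, spec)
  rootcause_over_units(comment$id, chunks$text, scorer, hyps, "CS2")
}

#' Build the summarize-then-list root-cause prompt
#'
#' Asks the chat model to first summarize why the person stopped, then list
#' the applicable categories, verbatim from the closed taxonomy, on a final
#' line starting with `Categories:`.
#'
#' @param comment_text Full comment text.
#' @return Prompt string.
#' @export
build_rootcause_prompt <- function(comment_text) {
  paste0(
    "You are reading a health-forum comment in which a person may have ",
    "stopped taking a medication. First, briefly summarize the reasons ",
    "for discontinuation. Then, on a final line starting with ",
    "'Categories:', list every applicable category, comma-separated, ",
    "using these names exactly:\n",
    paste(unname(rootcause_display_names()), collapse = ", "), "\n\n",
    "Comment:\n", comment_text
  )
}

#' Parse a chat response into a root-cause category set
#'
#' Reads the list after the last `Categories:` marker (or, failing that,
#' the last non-empty line), splits on commas/semicolons, and maps each name
#' to the closed taxonomy, ignoring case, whitespace, and punctuation.
#' Any unrecognized name makes the whole response unparseable
#' (`dde_parse_error`) so the caller can retry — names outside the taxonomy
#' are never silently dropped or fuzzily matched.
#'
#' @param raw Raw response text.
#' @return Character vector of category names (possibly empty if the model
#'   answered `Categories: none`).
#' @export
parse_rootcause_response <- function(raw) {
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  marked <- grep("categories\\s*:", lines, ignore.case = TRUE, value = TRUE)
  target <- if (length(marked) > 0L) {
    sub(".*[Cc]ategories\\s*:", "", marked[length(marked)])
  } else {
    nonempty <- lines[nzchar(trimws(lines))]
    if (length(nonempty) == 0L) {
      stop(parse_error("empty chat response", raw))
    }
    nonempty[length(nonempty)]
  }
  parts <- trimws(unlist(strsplit(target, "[,;]")))
  parts <- parts[nzchar(parts)]
  if (length(parts) == 1L && tolower(parts) %in% c("none", "no categories")) {
    return(character())
  }
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  lookup <- stats::setNames(rootcause_categories(),
                            norm(rootcause_display_names()))
  lookup2 <- stats::setNames(rootcause_categories(),
                             norm(rootcause_categories()))
  mapped <- vapply(parts, function(p) {
    key <- norm(p)
    if (key %in% names(lookup)) {
      lookup[[key]]
    } else if (key %in% names(lookup2)) {
      lookup2[[key]]
    } else {
      NA_character_
    }
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(mapped)) {
    stop(parse_error(
      paste0("unrecognized category name(s): ",
             paste(parts[is.na(mapped)], collapse = ", ")), raw))
  }
  unique(mapped)
}

#' Root causes via CS3 (whole comment, summarize-then-list)
#'
#' The whole comment goes to the chat backend; the response's category list
#' is parsed against the closed taxonomy. Unparseable responses are retried
#' per the scorer's retry budget, then recorded as missing (`categories`
#' `NA`), which the evaluation layer excludes with an explicit count.
#'
#' @param comment One-row comment tibble (or list with `id`, `text`).
#' @param scorer A [chat_scorer()].
#' @return One-row tibble as in [classify_rootcause_cs1()] with empty
#'   `per_category_scores` (chat backends are not score-producing).
#' @export
classify_rootcause_cs3 <- function(comment, scorer) {
  stopifnot(inherits(scorer, "dde_scorer"))
  if (scorer$backend != "chat") {
    stop("CS3 requires a chat backend scorer", call. = FALSE)
  }
  ans <- chat_ask(scorer, build_rootcause_prompt(comment$text),
                  parse_rootcause_response)
  cats <- if (is.null(ans)) NA_character_ else ans
  rootcause_result(comment$id, "CS3", cats, numeric())
}

#' Root-cause classification over a corpus
#'
#' @param comments Comment tibble.
#' @param scorer Scorer matching the strategy.
#' @param strategy `"CS1"`, `"CS2"`, or `"CS3"`.
#' @inheritParams classify_rootcause_cs2
#' @return Tibble with one row per comment.
#' @export
rootcause_corpus <- function(comments, scorer,
                             strategy = c("CS1", "CS2", "CS3"),
                             hyps = category_hypotheses(),
                             spec = tokenizer_spec(256L)) {
  strategy <- match.arg(strategy)
  rows <- lapply(seq_len(nrow(comments)), function(i) {
    cm <- comments[i, ]
    switch(strategy,
      CS1 = classify_rootcause_cs1(cm, scorer, hyps),
      CS2 = classify_rootcause_cs2(cm, scorer, hyps, spec),
      CS3 = classify_rootcause_cs3(cm, scorer)
    )
  })
  dplyr::bind_rows(rows)
}
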