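#' An entailment hypothesis
#'
#' The candidate statement whose entailment by a premise is scored. The
#' default detection hypothesis is "Person stopped taking medication."; note
#' that zero-shot results are sensitive to the hypothesis wording, so it is
#' configuration, never hard-coded downstream.
#'
#' @param text Hypothesis sentence; must be non-empty.
#' @param label Short identifier used for cue-table matching and reporting.
#' @return An object of class `dde_hypothesis`.
#' @export
hypothesis <- function(text, label = "dde") {
  stopifnot(is.character(text), nzchar(text))
  structure(list(text = text, label = label), class = "dde_hypothesis")
}

#' Default DDE-detection hypothesis
#' @return A [hypothesis()] with text "Person stopped taking medication."
#' @export
default_hypothesis <- function() {
  hypothesis("Person stopped taking medication.", label = "dde")
}

#' Deterministic mock entailment scorer
#'
#' A pure function of (premise, hypothesis, seed): if the lowercased premise
#' contains a cue phrase whose `label` matches the hypothesis label (or is
#' `NA`, meaning any hypothesis), the cue's score is returned, else
#' `baseline`. With flip probability `noise` > 0 the cue decision is
#' inverted, with the flip decided by a seeded hash of the
#' (premise, hypothesis) pair so identical inputs give identical scores
#' across processes.
#'
#' @param cue_table Tibble/data frame with columns `label` (hypothesis label,
#'   `NA` = any), `cue` (lowercase phrase matched as substring), `score`
#'   (value in \[0,1\] returned on a hit).
#' @param noise Flip probability in \[0, 1).
#' @param seed Integer seed entering the flip hash.
#' @param baseline Score returned when no cue matches.
#' @param hi Score reported when a flip turns a non-hit into a hit.
#' @return Scorer object of class `dde_scorer`.
#' @export
mock_scorer <- function(cue_table, noise = 0, seed = 0L, baseline = 0.01,
                        hi = 0.99) {
  stopifnot(is.data.frame(cue_table),
            all(c("label", "cue", "score") %in% names(cue_table)),
            noise >= 0, noise < 1)
  structure(
    list(backend = "mock", cue_table = tibble::as_tibble(cue_table),
         noise = noise, seed = as.integer(seed), baseline = baseline,
         hi = hi),
    class = "dde_scorer"
  )
}

#' Neural NLI scorer backend (plug point)
#'
#' Wraps a user-supplied entailment function (for example, one calling a
#' served zero-shot NLI model). The function receives `(premise,
#' hypothesis_text)` and must return a probability in \[0, 1\]. The default
#' offline path never loads a neural model: tests and synthetic experiments
#' run entirely on [mock_scorer()].
#'
#' @param score_fn Function `(premise, hypothesis_text) -> numeric in [0,1]`.
#' @param model_id Identifier recorded in outputs.
#' @param max_tokens Token budget of the underlying model.
#' @return Scorer object of class `dde_scorer`.
#' @export
nli_scorer <- function(score_fn, model_id = "user-nli", max_tokens = 512L) {
  if (!is.function(score_fn)) {
    stop("nli backend misconfigured: score_fn must be a function",
         call. = FALSE)
  }
  structure(
    list(backend = "nli", score_fn = score_fn, model_id = model_id,
         max_tokens = as.integer(max_tokens)),
    class = "dde_scorer"
  )
}

#' Chat-model scorer backend (plug point)
#'
#' Wraps a user-supplied completion function `prompt -> response text`. Chat
#' backends return hard 0/1 decisions parsed from text, never graded
#' probabilities, so threshold sweeps and AUCs are defined only for
#' score-producing backends. Unparseable responses are retried up to
#' `retries` times, after which a missing prediction is recorded — never a
#' silent default.
#'
#' @param complete_fn Function `prompt -> character` response.
#' @param model_id Identifier recorded in outputs.
#' @param retries Number of re-asks after an unparseable response.
#' @return Scorer object of class `dde_scorer`.
#' @export
chat_scorer <- function(complete_fn, model_id = "user-chat", retries = 2L) {
  if (!is.function(complete_fn)) {
    stop("chat backend misconfigured: complete_fn must be a function",
         call. = FALSE)
  }
  structure(
    list(backend = "chat", complete_fn = complete_fn, model_id = model_id,
         retries = as.integer(retries)),
    class = "dde_scorer"
  )
}

#' Score entailment of a hypothesis by a premise
#'
#' @param premise Premise text (a sentence, chunk, or whole comment).
#' @param hyp A [hypothesis()].
#' @param scorer A scorer from [mock_scorer()] or [nli_scorer()].
#' @return Probability in \[0, 1\].
#' @export
score_entailment <- function(premise, hyp, scorer) {
  stopifnot(inherits(scorer, "dde_scorer"), inherits(hyp, "dde_hypothesis"))
  switch(scorer$backend,
    mock = score_mock(premise, hyp, scorer),
    nli = {
      val <- scorer$score_fn(premise, hyp$text)
      if (!is.numeric(val) || is.na(val) || val < 0 || val > 1) {
        stop("nli backend transport failure: score_fn returned ",
             deparse(val), " (expected a probability)", call. = FALSE)
      }
      as.numeric(val)
    },
    chat = stop(
      "chat backends produce binary decisions, not entailment ",
      "probabilities; use classify_cs3()", call. = FALSE
    ),
    stop("unknown scorer backend: ", scorer$backend, call. = FALSE)
  )
}

score_mock <- function(premise, hyp, scorer) {
  ct <- scorer$cue_table
  rel <- is.na(ct$label) | ct$label == hyp$label
  low <- tolower(premise)
  hit_scores <- ct$score[rel][vapply(ct$cue[rel], function(cue) {
    grepl(cue, low, fixed = TRUE)
  }, logical(1))]
  matched <- length(hit_scores) > 0L
  if (scorer$noise > 0) {
    u <- fnv1a_uniform(paste(premise, hyp$text, scorer$seed, sep = "\x1f"))
    if (u < scorer$noise) matched <- !matched
    if (matched && length(hit_scores) == 0L) return(scorer$hi)
  }
  if (matched) max(hit_scores) else scorer$baseline
}

# FNV-1a 32-bit hash mapped to [0,1); pure R, stable across processes.
# 32-bit modular multiply done in 16-bit halves to stay inside exact doubles.
fnv1a_uniform <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2(h, b)
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h / 4294967296
}

# xor for non-negative doubles < 2^32 (base bitwXor is 32-bit signed)
bitwXor2 <- function(a, b) {
  hi_a <- floor(a / 65536); lo_a <- a - hi_a * 65536
  hi_b <- floor(b / 65536); lo_b <- b - hi_b * 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

#' Build the binary DDE-detection prompt
#'
#' Instructs the chat model to answer with a single character, 1 (the
#' comment reports that a specific person stopped a recurring medication or
#' treatment) or 0 (it does not), and embeds the comment verbatim.
#'
#' @param comment_text Full comment text.
#' @return Prompt string.
#' @export
build_binary_prompt <- function(comment_text) {
  paste0(
    "You are reading a health-forum comment. Decide whether it reports a ",
    "drug discontinuation event: a specific person stopped taking a ",
    "recurring medication or treatment (a medication change counts; a ",
    "one-time treatment does not).\n",
    "Answer with exactly one character and nothing else: 1 if the comment ",
    "contains a drug discontinuation event, 0 if it does not.\n\n",
    "Comment:\n", comment_text
  )
}

#' Parse a chat response into a binary label
#'
#' Extracts the first standalone 0 or 1 (not embedded in a longer number);
#' anything else raises a condition of class `dde_parse_error` carrying the
#' raw response so the caller can retry or record a missing prediction.
#'
#' @param raw Raw response text.
#' @return Integer 0 or 1.
#' @export
parse_binary_response <- function(raw) {
  m <- regmatches(raw, regexpr("(?<![0-9])[01](?![0-9])", raw, perl = TRUE))
  if (length(m) == 0L) {
    stop(parse_error("no standalone 0/1 token in chat response", raw))
  }
  as.integer(m)
}

parse_error <- function(msg, raw) {
  structure(
    class = c("dde_parse_error", "error", "condition"),
    list(message = paste0(msg, "; raw response: ", substr(raw, 1, 200)),
         call = NULL, raw = raw)
  )
}

# ask the chat backend, retrying on unparseable output; returns NA_integer_
# (a recorded missing prediction) after retries are exhausted
chat_ask <- function(scorer, prompt, parser) {
  for (i in seq_len(scorer$retries + 1L)) {
    raw <- scorer$complete_fn(prompt)
    out <- tryCatch(parser(raw), dde_parse_error = function(e) e)
    if (!inherits(out, "dde_parse_error")) return(out)
  }
  NULL
}
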