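#' Configuration for the synthetic forum-corpus generator
#'
#' The generator emulates the statistical structure of a labeled
#' pharmacovigilance forum corpus: multi-sentence comments, a DDE prevalence
#' of 10.7% by default, multilabel root-cause frequencies defaulting to the
#' observed per-1000 rates (personal choices 670, adverse reactions 627,
#' alternative medical reasons 418, treatment inefficacy 250, accessibility
#' issues 119, indeterminate 103, non-discontinuation 100, treatment success
#' 96), and hard negatives of the documented failure type ("I am not on any
#' medication"). The positive count is planted exactly as
#' `round(n_comments * dde_prevalence)` so small corpora have deterministic
#' class counts; the seed fully determines the output.
#'
#' @param n_comments Number of comments to generate.
#' @param dde_prevalence Fraction of DDE comments, default 0.107.
#' @param rootcause_weights Named inclusion probabilities per category
#'   (independent per category, with at least one forced per DDE comment).
#' @param sentences_per_comment Integer range (length-2) of sentences per
#'   comment, default 2 to 6.
#' @param hard_negative_rate Fraction of non-DDE comments containing
#'   negated-medication phrasing, default 0.10.
#' @param noise Flip probability passed along to the matched mock scorer.
#' @param seed Integer seed.
#' @return List of class `dde_synthetic_config`.
#' @export
synthetic_config <- function(n_comments,
                             dde_prevalence = 0.107,
                             rootcause_weights = default_rootcause_weights(),
                             sentences_per_comment = c(2L, 6L),
                             hard_negative_rate = 0.10,
                             noise = 0,
                             seed = 20260101L) {
  stopifnot(n_comments >= 1,
            dde_prevalence >= 0, dde_prevalence <= 1,
            length(sentences_per_comment) == 2L,
            sentences_per_comment[1] >= 1,
            sentences_per_comment[2] >= sentences_per_comment[1],
            hard_negative_rate >= 0, hard_negative_rate <= 1,
            noise >= 0, noise < 1)
  if (!setequal(names(rootcause_weights), rootcause_categories()) ||
      any(rootcause_weights < 0) || any(rootcause_weights > 1)) {
    stop("rootcause_weights must name all 8 categories with values in [0,1]",
         call. = FALSE)
  }
  structure(list(
    n_comments = as.integer(n_comments),
    dde_prevalence = dde_prevalence,
    rootcause_weights = rootcause_weights[rootcause_categories()],
    sentences_per_comment = as.integer(sentences_per_comment),
    hard_negative_rate = hard_negative_rate,
    noise = noise,
    seed = as.integer(seed)
  ), class = "dde_synthetic_config")
}

#' Default root-cause inclusion probabilities
#'
#' The observed per-1000 annotation frequencies of the eight categories,
#' scaled to probabilities.
#'
#' @return Named numeric vector over [rootcause_categories()].
#' @export
default_rootcause_weights <- function() {
  c(treatment_success = 0.096, treatment_inefficacy = 0.250,
    adverse_reactions = 0.627, accessibility_issues = 0.119,
    personal_choices = 0.670, alternative_medical_reasons = 0.418,
    indeterminate = 0.103, non_discontinuation = 0.100)
}

synthetic_drugs <- function() {
  c("lipitor", "metformin", "zoloft", "prozac", "lisinopril", "xanax",
    "plavix", "advair")
}

# detection cue phrases: any of these in a sentence marks it as a
# discontinuation statement
detection_cues <- function() {
  c("stopped taking", "quit taking", "discontinued")
}

# per-category cue phrase and sentence template ({drug}, {n} substituted);
# every template except non_discontinuation also carries a detection cue
category_templates <- function() {
  tibble::tibble(
    category = rootcause_categories(),
    cue = c("treatment worked", "did not help", "side effects",
            "could not afford", "wanted a break", "switched me to",
            "cannot say exactly why", "still taking"),
    template = c(
      "I stopped taking {drug} after {n} days because the treatment worked and I feel cured.",
      "I stopped taking {drug} after {n} days because it did not help me at all.",
      "I stopped taking {drug} {n} days ago because of the side effects.",
      "I stopped taking {drug} after {n} days because I could not afford the refill.",
      "I stopped taking {drug} {n} days ago because I just wanted a break from pills.",
      "I stopped taking {drug} after {n} days because my doctor switched me to something else.",
      "I stopped taking {drug} about {n} days ago and cannot say exactly why.",
      "I am still taking {drug} every single day after {n} days."
    )
  )
}

# every template carries {drug} and {n} draws so generated sentences are
# near-unique; flip decisions in the seeded mock then behave independently
background_templates <- function() {
  c("I have been on {drug} for {n} days now.",
    "My doctor first prescribed {drug} about {n} days ago.",
    "Has anyone here used {drug} for more than {n} days?",
    "The pharmacy filled my {drug} prescription in {n} minutes.",
    "I take {drug} with breakfast, going on {n} days now.",
    "My sister used {drug} for about {n} days and we compare notes.")
}

hard_negative_templates <- function() {
  c("I am not on any medication right now, and have not been for {n} days.",
    "I have never taken any medication for this problem in {n} years.")
}

generic_dde_template <- function() {
  "I finally stopped taking it {n} days ago."
}

fill_template <- function(template) {
  out <- gsub("{drug}", sample(synthetic_drugs(), 1L), template, fixed = TRUE)
  gsub("{n}", sample(500L, 1L), out, fixed = TRUE)
}

#' Generate a synthetic forum corpus with planted gold labels
#'
#' DDE comments embed one cue sentence per sampled root-cause category (each
#' category included independently with its weight; at least one forced by a
#' weighted draw); a comment whose only sampled category carries no
#' discontinuation phrasing additionally gets a generic discontinuation
#' sentence, so every DDE comment contains at least one detection cue.
#' Non-DDE comments are background sentences, a configurable fraction of
#' which include a negated-medication hard negative. Three simulated
#' annotators disagree on 8.9% of comments and report confidence levels at
#' the observed rates (96.33 / 3.4 / 0.27%). The manifest echoes the config
#' and carries the cue table that [matched_mock_scorer()] consumes.
#'
#' @param config A [synthetic_config()].
#' @return List of class `dde_corpus`: `comments`, `gold_binary`,
#'   `gold_rootcause` (one row per DDE comment), `manifest`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "dde_synthetic_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_comments
  n_pos <- round(n * config$dde_prevalence)
  pos_idx <- if (n_pos > 0) sort(sample.int(n, n_pos)) else integer()
  is_pos <- seq_len(n) %in% pos_idx
  tmpl <- category_templates()
  weights <- config$rootcause_weights
  srange <- config$sentences_per_comment

  texts <- character(n)
  cat_sets <- vector("list", n)
  for (i in seq_len(n)) {
    m_target <- sample(seq(srange[1], srange[2]), 1L)
    if (is_pos[i]) {
      inc <- stats::runif(8L) < weights
      if (!any(inc)) {
        inc[sample.int(8L, 1L, prob = weights)] <- TRUE
      }
      cats <- rootcause_categories()[inc]
      cat_sets[[i]] <- cats
      cues <- vapply(tmpl$template[match(cats, tmpl$category)], fill_template,
                     character(1), USE.NAMES = FALSE)
      if (all(cats == "non_discontinuation")) {
        cues <- c(cues, fill_template(generic_dde_template()))
      }
      n_bg <- max(0L, m_target - length(cues))
      bg <- vapply(sample(background_templates(), n_bg, replace = TRUE),
                   fill_template, character(1), USE.NAMES = FALSE)
      texts[i] <- paste(sample(c(cues, bg)), collapse = " ")
    } else {
      n_bg <- m_target
      sents <- vapply(sample(background_templates(), n_bg, replace = TRUE),
                      fill_template, character(1), USE.NAMES = FALSE)
      if (stats::runif(1) < config$hard_negative_rate) {
        sents[sample.int(length(sents), 1L)] <-
          sample(hard_negative_templates(), 1L)
      }
      texts[i] <- paste(sents, collapse = " ")
    }
  }

  ids <- sprintf("c%05d", seq_len(n))
  comments <- tibble::tibble(id = ids, text = texts, source = "synthetic")

  truth <- as.integer(is_pos)
  labels <- lapply(seq_len(n), function(i) {
    lab <- rep(truth[i], 3L)
    if (stats::runif(1) < 0.089) {
      j <- sample.int(3L, 1L)
      lab[j] <- 1L - lab[j]
    }
    lab
  })
  confidences <- lapply(seq_len(n), function(i) {
    sample(confidence_levels(), 3L, replace = TRUE,
           prob = c(0.9633, 0.034, 0.0027))
  })
  gold_binary <- tibble::tibble(
    comment_id = ids,
    consensus = vapply(labels, majority_vote, integer(1)),
    labels = labels,
    confidences = confidences
  )

  gold_rootcause <- tibble::tibble(
    comment_id = ids[is_pos],
    categories = cat_sets[is_pos]
  )

  cue_table <- dplyr::bind_rows(
    tibble::tibble(label = "dde", cue = detection_cues(), score = 0.99),
    tibble::tibble(label = tmpl$category, cue = tmpl$cue, score = 0.99)
  )
  manifest <- list(
    generator = "ddetect-synthetic",
    version = 1L,
    seed = config$seed,
    noise = config$noise,
    n_comments = n,
    n_positive = n_pos,
    dde_prevalence = config$dde_prevalence,
    rootcause_weights = as.list(config$rootcause_weights),
    sentences_per_comment = config$sentences_per_comment,
    hard_negative_rate = config$hard_negative_rate,
    cue_table = cue_table,
    lexicon = c(synthetic_drugs(), "medication")
  )
  structure(list(comments = comments, gold_binary = gold_binary,
                 gold_rootcause = gold_rootcause, manifest = manifest),
            class = "dde_corpus")
}

#' Mock scorer matched to a synthetic corpus
#'
#' Builds a [mock_scorer()] whose cue table is the one the generator planted
#' (detection cues for the detection hypothesis; one cue per root-cause
#' category). With `noise = 0`, CS1 at any cutoff strictly between the
#' baseline (0.01) and the cue score (0.99) recovers the planted gold
#' exactly, for detection and for root-cause sets.
#'
#' @param corpus A `dde_corpus` (or its `manifest`).
#' @param noise Flip probability; defaults to the noise recorded in the
#'   manifest.
#' @return A `dde_scorer` (mock backend).
#' @export
matched_mock_scorer <- function(corpus, noise = NULL) {
  manifest <- if (inherits(corpus, "dde_corpus")) corpus$manifest else corpus
  if (!identical(manifest$generator, "ddetect-synthetic") ||
      !identical(manifest$version, 1L)) {
    stop("manifest does not come from this generator version", call. = FALSE)
  }
  mock_scorer(manifest$cue_table,
              noise = noise %||% manifest$noise,
              seed = manifest$seed)
}

#' Closed-form expected comment-level false negative rate under noise
#'
#' Under CS1 with the matched mock scorer at flip probability `eps`, a DDE
#' comment with `k` cue-bearing sentences out of `m` total is missed exactly
#' when all `k` cue decisions flip off and none of the `m - k` others flips
#' on: probability `eps^k * (1 - eps)^(m - k)`. The corpus-level expectation
#' averages this over the planted DDE comments.
#'
#' @param corpus A `dde_corpus`.
#' @param eps Flip probability in \[0, 1).
#' @return Expected comment-level FNR.
#' @export
expected_cs1_fnr <- function(corpus, eps) {
  stopifnot(inherits(corpus, "dde_corpus"), eps >= 0, eps < 1)
  pos_ids <- corpus$gold_binary$comment_id[corpus$gold_binary$consensus == 1L]
  pos <- corpus$comments[corpus$comments$id %in% pos_ids, ]
  cues <- detection_cues()
  miss_p <- vapply(pos$text, function(txt) {
    sents <- split_sentences(txt)$text
    k <- sum(vapply(sents, function(s) {
      any(vapply(cues, grepl, logical(1), x = tolower(s), fixed = TRUE))
    }, logical(1)))
    m <- length(sents)
    eps^k * (1 - eps)^(m - k)
  }, numeric(1), USE.NAMES = FALSE)
  mean(miss_p)
}
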