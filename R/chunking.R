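#' Tokenizer specification
#'
#' Names the token-counting scheme and the maximum token budget of the target
#' scorer. The default `"words"` scheme counts maximal alphanumeric runs and
#' each punctuation mark as one token; a neural backend can expose its own
#' tokenizer through `count_fn` under the same contract.
#'
#' @param max_tokens Positive integer token budget.
#' @param name Scheme identifier; only `"words"` is built in.
#' @param count_fn Optional function `text -> integer` overriding the scheme.
#' @return An object of class `dde_tokenizer_spec`.
#' @export
tokenizer_spec <- function(max_tokens, name = "words", count_fn = NULL) {
  stopifnot(is.numeric(max_tokens), length(max_tokens) == 1L, max_tokens >= 1)
  structure(
    list(name = name, max_tokens = as.integer(max_tokens), count_fn = count_fn),
    class = "dde_tokenizer_spec"
  )
}

# token spans under the "words" scheme: maximal alphanumeric runs, and each
# punctuation mark separately; whitespace is not a token
token_spans <- function(text) {
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Count tokens in a text
#'
#' @param text Character scalar.
#' @param spec A [tokenizer_spec()].
#' @return Non-negative integer token count.
#' @export
count_tokens <- function(text, spec) {
  stopifnot(inherits(spec, "dde_tokenizer_spec"))
  if (!is.null(spec$count_fn)) {
    return(as.integer(spec$count_fn(text)))
  }
  if (spec$name != "words") {
    stop("unknown token-counting scheme: ", spec$name, call. = FALSE)
  }
  nrow(token_spans(text))
}

#' Split a comment into sentences
#'
#' Deterministic rule-based segmentation, approximating an off-the-shelf
#' sentencizer: a boundary occurs after a run of sentence-final punctuation
#' (`.`, `!`, `?`) followed by whitespace or end of text. A period followed
#' (after whitespace) by a lowercase letter does not split, which keeps
#' abbreviations like "e.g. this" together. Text with no terminal
#' punctuation yields a single span. Spans carry 0-based half-open character
#' offsets into the original text; the text between consecutive spans is
#' whitespace only, so the original string can be reconstructed from the
#' spans and their separators.
#'
#' @param text Comment text (may be empty).
#' @param spec Optional [tokenizer_spec()]; when given, a `token_count`
#'   column is added.
#' @return Tibble with `text`, `start`, `end` (and optionally `token_count`);
#'   zero rows for empty/whitespace-only input.
#' @export
split_sentences <- function(text, spec = NULL) {
  empty <- tibble::tibble(text = character(), start = integer(),
                          end = integer())
  if (is.na(text) || !nzchar(trimws(text))) {
    if (!is.null(spec)) empty$token_count <- integer()
    return(empty)
  }
  # zero-width split points: after !? before whitespace, or after . before
  # whitespace not followed by a lowercase letter
  pat <- "(?:(?<=[!?])(?=\\s))|(?:(?<=\\.)(?=\\s)(?!\\s*[a-z]))"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer() else as.integer(m)  # split before cuts[i]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(text))
  spans <- lapply(seq_along(starts), function(i) {
    seg <- substr(text, starts[i], ends[i])
    # trim to non-whitespace extent, keeping absolute offsets
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- starts[i] + lead
    e <- ends[i] - trail
    if (e < s) return(NULL)
    tibble::tibble(text = substr(text, s, e), start = s - 1L, end = e)
  })
  out <- dplyr::bind_rows(spans)
  if (nrow(out) == 0L) out <- empty
  if (!is.null(spec)) {
    out$token_count <- vapply(out$text, count_tokens, integer(1), spec = spec,
                              USE.NAMES = FALSE)
  }
  out
}

#' Pack consecutive sentences into token-budget chunks
#'
#' Greedy left-to-right packing: the current chunk is extended while adding
#' the next sentence keeps the total token count within `max_tokens`,
#' otherwise a new chunk starts. A single sentence longer than the budget is
#' force-split into token windows of at most `max_tokens` tokens, each
#' flagged `overflow`. Sentences within a chunk are joined with a single
#' space. Every sentence appears in exactly one chunk (or one overflow
#' window group), in order.
#'
#' @param sentences Sentence tibble from [split_sentences()].
#' @param spec A [tokenizer_spec()] carrying the budget.
#' @return Tibble with `chunk_index`, list-column `sentence_indices`, `text`,
#'   `token_count`, `overflow`.
#' @export
group_sentences <- function(sentences, spec) {
  stopifnot(inherits(spec, "dde_tokenizer_spec"))
  empty <- tibble::tibble(chunk_index = integer(), sentence_indices = list(),
                          text = character(), token_count = integer(),
                          overflow = logical())
  n <- nrow(sentences)
  if (n == 0L) return(empty)
  counts <- if ("token_count" %in% names(sentences)) {
    sentences$token_count
  } else {
    vapply(sentences$text, count_tokens, integer(1), spec = spec,
           USE.NAMES = FALSE)
  }
  budget <- spec$max_tokens
  chunks <- list()
  cur <- integer()
  cur_tokens <- 0L
  flush <- function() {
    if (length(cur) > 0L) {
      chunks[[length(chunks) + 1L]] <<- list(
        idx = cur, text = paste(sentences$text[cur], collapse = " "),
        tokens = cur_tokens, overflow = FALSE
      )
    }
    cur <<- integer(); cur_tokens <<- 0L
  }
  for (i in seq_len(n)) {
    if (counts[i] > budget) {
      flush()
      for (w in overflow_windows(sentences$text[i], budget)) {
        chunks[[length(chunks) + 1L]] <- list(
          idx = i, text = w$text, tokens = w$tokens, overflow = TRUE
        )
      }
    } else if (cur_tokens + counts[i] <= budget) {
      cur <- c(cur, i)
      cur_tokens <- cur_tokens + counts[i]
    } else {
      flush()
      cur <- i
      cur_tokens <- counts[i]
    }
  }
  flush()
  tibble::tibble(
    chunk_index = seq_along(chunks),
    sentence_indices = lapply(chunks, `[[`, "idx"),
    text = vapply(chunks, `[[`, character(1), "text"),
    token_count = vapply(chunks, function(c) as.integer(c$tokens), integer(1)),
    overflow = vapply(chunks, `[[`, logical(1), "overflow")
  )
}

# hard-window an oversized sentence at token boundaries under the words scheme
overflow_windows <- function(text, budget) {
  spans <- token_spans(text)
  k <- nrow(spans)
  starts <- seq(1L, k, by = budget)
  lapply(starts, function(s) {
    e <- min(s + budget - 1L, k)
    list(text = substr(text, spans$start[s], spans$end[e]),
         tokens = e - s + 1L)
  })
}
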