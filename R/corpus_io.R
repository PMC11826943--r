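#' Read forum comments from JSONL or CSV
#'
#' A comment is one forum question or answer: a unique `id`, the raw `text`
#' (which may be empty, contain typos, or lack punctuation), and an optional
#' `source` community/thread identifier. Missing optional fields default to
#' the empty string; record order is preserved.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (header row
#'   with columns `id`, `text`, optionally `source`).
#' @return A tibble with character columns `id`, `text`, `source`.
#' @export
read_comments <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("comment file not found: ", path, call. = FALSE)
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(empty_comments())
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
        error = function(e) stop(
          "malformed JSONL record at line ", i, ": ", conditionMessage(e),
          call. = FALSE
        )
      )
      if (is.null(rec$id) || is.null(rec$text)) {
        stop("record at line ", i, " lacks required field(s) id/text",
             call. = FALSE)
      }
      tibble::tibble(
        id = as.character(rec$id),
        text = as.character(rec$text),
        source = as.character(rec$source %||% "")
      )
    })
    out <- dplyr::bind_rows(recs)
  } else {
    out <- suppressWarnings(
      readr::read_csv(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    )
    probs <- readr::problems(out)
    if (nrow(probs) > 0L) {
      stop("malformed CSV record at line ", probs$row[[1]], ": expected ",
           probs$expected[[1]], call. = FALSE)
    }
    if (nrow(out) == 0L) return(empty_comments())
    if (!all(c("id", "text") %in% names(out))) {
      stop("CSV is missing required column(s): ",
           paste(setdiff(c("id", "text"), names(out)), collapse = ", "),
           call. = FALSE)
    }
    bad <- which(is.na(out$text) | is.na(out$id))
    if (length(bad) > 0L) {
      stop("CSV row missing id/text value at line ", bad[[1]] + 1L,
           call. = FALSE)
    }
    out <- tibble::tibble(
      id = out$id,
      text = out$text,
      source = if ("source" %in% names(out)) {
        dplyr::coalesce(out$source, "")
      } else {
        ""
      }
    )
  }
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0L) {
    stop("duplicate comment id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out
}

empty_comments <- function() {
  tibble::tibble(id = character(), text = character(), source = character())
}

#' Write comments to JSONL or CSV
#'
#' @param comments Tibble with columns `id`, `text`, and optionally `source`.
#' @inheritParams read_comments
#' @return `path`, invisibly.
#' @export
write_comments <- function(comments, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!"source" %in% names(comments)) comments$source <- ""
  comments <- comments[, c("id", "text", "source")]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(comments)), function(i) {
      jsonlite::toJSON(as.list(comments[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(comments, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a drug-keyword lexicon
#'
#' Plain text, one term per line; blank lines and lines starting with `#` are
#' ignored; terms are trimmed and lowercased. Multi-word terms are allowed and
#' are later matched as contiguous phrases.
#'
#' @param path Path to the lexicon file.
#' @return Character vector of lowercase terms.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- trimws(lines)
  terms <- terms[nzchar(terms) & !startsWith(terms, "#")]
  unique(tolower(terms))
}

#' Keep only comments mentioning a lexicon term
#'
#' Keyword prefilter applied before any scoring: a comment is retained when
#' its text contains at least one lexicon term as a whole word (term
#' boundaries are non-alphanumeric characters), case-insensitively.
#' Multi-word terms match as contiguous phrases with flexible internal
#' whitespace. Substring hits inside longer words ("aspirin" in "aspiring")
#' do not count.
#'
#' @param comments Comment tibble (see [read_comments()]).
#' @param lexicon Character vector of terms (see [read_lexicon()]).
#' @return The retained rows of `comments`, in input order.
#' @export
keyword_filter <- function(comments, lexicon) {
  if (length(lexicon) == 0L) {
    stop("lexicon is empty; filtering would retain nothing meaningful",
         call. = FALSE)
  }
  pats <- vapply(lexicon, term_pattern, character(1))
  keep <- vapply(comments$text, function(txt) {
    any(vapply(pats, function(p) grepl(p, txt, perl = TRUE, ignore.case = TRUE),
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  comments[keep, , drop = FALSE]
}

term_pattern <- function(term) {
  parts <- strsplit(trimws(term), "\\s+")[[1]]
  body <- paste0("\\Q", parts, "\\E", collapse = "\\s+")
  paste0("(?<![[:alnum:]])", body, "(?![[:alnum:]])")
}

#' Majority vote over an odd panel of binary annotations
#'
#' @param labels Vector of 0/1 annotator labels; must be odd-length so the
#'   majority is defined (ties in the source data were resolved by
#'   discussion, not by vote).
#' @return 0 or 1, the value held by more than half the annotators.
#' @export
majority_vote <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) %% 2L == 0L) {
    stop("majority vote needs an odd number of annotators, got ",
         length(labels), call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  as.integer(sum(labels) > length(labels) / 2)
}

#' Annotator confidence levels
#' @return Character vector of the three levels, most to least confident.
#' @export
confidence_levels <- function() {
  c("very_confident", "somewhat_confident", "not_confident")
}

#' Tabulate annotator confidence levels
#'
#' @param confidences Character vector of values in [confidence_levels()].
#' @return Tibble with `level`, `count`, and `percent` (100 * count / total,
#'   rounded half-up to 2 decimals).
#' @export
confidence_summary <- function(confidences) {
  if (length(confidences) == 0L) {
    stop("no confidence values supplied", call. = FALSE)
  }
  bad <- setdiff(unique(confidences), confidence_levels())
  if (length(bad) > 0L) {
    stop("unknown confidence level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(confidences, levels = confidence_levels()))
  tibble::tibble(
    level = names(counts),
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / length(confidences), 2)
  )
}

#' Read gold binary DDE labels
#'
#' Expects columns `comment_id`, `label_1..label_k`, `conf_1..conf_k` (CSV
#' with header, or JSONL with the same keys). The consensus label is the
#' majority vote over the `label_*` columns.
#'
#' @inheritParams read_comments
#' @return Tibble with `comment_id`, `consensus`, list-columns `labels` and
#'   `confidences`.
#' @export
read_gold_binary <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  raw <- read_flat_records(path, format)
  label_cols <- sort(grep("^label_[0-9]+$", names(raw), value = TRUE))
  conf_cols <- sort(grep("^conf_[0-9]+$", names(raw), value = TRUE))
  if (length(label_cols) == 0L || !"comment_id" %in% names(raw)) {
    stop("gold binary file needs comment_id and label_1..k columns",
         call. = FALSE)
  }
  if (length(conf_cols) > 0L && length(conf_cols) != length(label_cols)) {
    stop("labels and confidences have different annotator counts",
         call. = FALSE)
  }
  labels <- lapply(seq_len(nrow(raw)), function(i) {
    as.integer(unlist(raw[i, label_cols]))
  })
  confidences <- if (length(conf_cols) > 0L) {
    lapply(seq_len(nrow(raw)), function(i) as.character(unlist(raw[i, conf_cols])))
  } else {
    rep(list(character()), nrow(raw))
  }
  tibble::tibble(
    comment_id = as.character(raw$comment_id),
    consensus = vapply(labels, majority_vote, integer(1)),
    labels = labels,
    confidences = confidences
  )
}

#' Write gold binary DDE labels
#'
#' @param gold Tibble as returned by [read_gold_binary()].
#' @inheritParams read_gold_binary
#' @return `path`, invisibly.
#' @export
write_gold_binary <- function(gold, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  k <- length(gold$labels[[1]])
  flat <- tibble::tibble(comment_id = gold$comment_id)
  for (j in seq_len(k)) {
    flat[[paste0("label_", j)]] <- vapply(gold$labels, `[[`, integer(1), j)
  }
  kc <- length(gold$confidences[[1]])
  for (j in seq_len(kc)) {
    flat[[paste0("conf_", j)]] <- vapply(gold$confidences, `[[`, character(1), j)
  }
  write_flat_records(flat, path, format)
}

#' Read gold multilabel root-cause annotations
#'
#' Expects columns `comment_id` and `categories`; in CSV the categories are a
#' `;`-separated list of enumeration names, in JSONL a JSON array.
#'
#' @inheritParams read_comments
#' @return Tibble with `comment_id` and list-column `categories`.
#' @export
read_gold_rootcause <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  raw <- read_flat_records(path, format, list_cols = "categories")
  if (!all(c("comment_id", "categories") %in% names(raw))) {
    stop("gold root-cause file needs comment_id and categories columns",
         call. = FALSE)
  }
  cats <- lapply(raw$categories, function(x) {
    x <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
    x <- trimws(x[nzchar(trimws(x))])
    bad <- setdiff(x, rootcause_categories())
    if (length(bad) > 0L) {
      stop("unknown root-cause categor(ies): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x
  })
  tibble::tibble(comment_id = as.character(raw$comment_id), categories = cats)
}

#' Write gold multilabel root-cause annotations
#'
#' @param gold Tibble with `comment_id` and list-column `categories`.
#' @inheritParams read_gold_rootcause
#' @return `path`, invisibly.
#' @export
write_gold_rootcause <- function(gold, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  flat <- tibble::tibble(
    comment_id = gold$comment_id,
    categories = vapply(gold$categories, paste, character(1), collapse = ";")
  )
  write_flat_records(flat, path, format)
}

read_flat_records <- function(path, format, list_cols = character()) {
  if (format == "csv") {
    out <- suppressWarnings(
      readr::read_csv(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    )
    probs <- readr::problems(out)
    if (nrow(probs) > 0L) {
      stop("malformed CSV record at line ", probs$row[[1]], call. = FALSE)
    }
    out
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) {
        stop("malformed JSONL record at line ", i, call. = FALSE)
      })
      for (lc in intersect(list_cols, names(rec))) {
        rec[[lc]] <- paste(rec[[lc]], collapse = ";")
      }
      tibble::as_tibble(rec)
    })
    dplyr::bind_rows(recs)
  }
}

write_flat_records <- function(flat, path, format) {
  if (format == "csv") {
    readr::write_csv(flat, path, progress = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(flat)), function(i) {
      jsonlite::toJSON(as.list(flat[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

# round half away from zero at the given number of decimals; base round()
# uses banker's rounding, which disagrees with how rates are printed
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
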