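# shared fixtures: tiny corpora, cue tables, and independent oracles

tiny_cue_table <- function() {
  tibble::tibble(
    label = c("dde", "dde", "adverse_reactions", "accessibility_issues"),
    cue = c("stopped taking", "quit", "side effects", "could not afford"),
    score = c(0.99, 0.97, 0.96, 0.98)
  )
}

tiny_comments <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    text = c(
      "I feel fine today. I stopped taking lipitor. Thanks all.",
      "Has anyone tried metformin? My doctor loves it.",
      "I quit because of the side effects. I could not afford it either."
    ),
    source = ""
  )
}

# brute-force greedy packer: the independent oracle for group_sentences on
# within-budget sentences (no overflow)
oracle_greedy_pack <- function(counts, budget) {
  chunks <- list()
  cur <- integer(); tot <- 0L
  for (i in seq_along(counts)) {
    if (length(cur) > 0L && tot + counts[i] > budget) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(); tot <- 0L
    }
    cur <- c(cur, i); tot <- tot + counts[i]
  }
  if (length(cur) > 0L) chunks[[length(chunks) + 1L]] <- cur
  chunks
}

# pairwise-concordance AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, gold) {
  pos <- scores[gold == 1L]
  neg <- scores[gold == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# brute-force pooled multilabel averages over membership matrices
oracle_multilabel_f1 <- function(pm, gm) {
  per <- vapply(seq_len(ncol(pm)), function(j) {
    tp <- sum(pm[, j] == 1 & gm[, j] == 1)
    fp <- sum(pm[, j] == 1 & gm[, j] == 0)
    fn <- sum(pm[, j] == 0 & gm[, j] == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- colSums(gm)
  tp <- sum(pm == 1 & gm == 1)
  fp <- sum(pm == 1 & gm == 0)
  fn <- sum(pm == 0 & gm == 1)
  list(
    micro = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    macro = mean(per),
    weighted = sum(per * support / sum(support))
  )
}

random_multilabel_instance <- function(n, k = 8L) {
  cats <- paste0("k", seq_len(k))
  draw <- function() {
    lapply(seq_len(n), function(i) cats[stats::runif(k) < 0.3])
  }
  list(cats = cats,
       pred = tibble::tibble(comment_id = as.character(seq_len(n)),
                             categories = draw()),
       gold = tibble::tibble(comment_id = as.character(seq_len(n)),
                             categories = draw()))
}

member_matrix <- function(sets, cats) {
  t(vapply(sets, function(s) as.integer(cats %in% s), integer(length(cats))))
}
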