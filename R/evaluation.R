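#' Confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `dde_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(as.list(counts), class = "dde_confusion")
}

#' Confusion matrix from aligned label vectors
#'
#' `NA` predictions (recorded missing values, e.g. persistently unparseable
#' chat responses) are excluded, and the exclusion count is attached as
#' attribute `excluded` — they are never imputed.
#'
#' @param pred,gold Aligned 0/1 vectors; `pred` may contain `NA`.
#' @return A `dde_confusion` with attribute `excluded`.
#' @export
confusion_from_labels <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  keep <- !is.na(pred)
  p <- pred[keep]; g <- gold[keep]
  out <- confusion_matrix(
    tp = sum(p == 1L & g == 1L), fp = sum(p == 1L & g == 0L),
    fn = sum(p == 0L & g == 1L), tn = sum(p == 0L & g == 0L)
  )
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Binary classification rates from a confusion matrix
#'
#' Computes precision, recall (= TPR), F1, accuracy, FPR, FNR, TNR. A rate
#' whose denominator is zero is reported as 0 and its name listed in the
#' `degenerate` field, keeping reports machine-readable instead of emitting
#' `NaN`.
#'
#' @param cm A [confusion_matrix()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return List of class `dde_binary_metrics`: the seven rates plus
#'   `total`, `excluded`, and `degenerate` (character vector of flagged
#'   rate names).
#' @export
binary_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- character()
  rate <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else {
      num / den
    }
  }
  precision <- rate(tp, tp + fp, "precision")
  recall <- rate(tp, tp + fn, "recall")
  f1 <- rate(2 * tp, 2 * tp + fp + fn, "f1")
  structure(list(
    precision = precision,
    recall = recall,
    f1 = f1,
    accuracy = (tp + tn) / total,
    fpr = rate(fp, fp + tn, "fpr"),
    fnr = rate(fn, fn + tp, "fnr"),
    tpr = recall,
    tnr = rate(tn, tn + fp, "tnr"),
    total = total,
    excluded = attr(cm, "excluded") %||% 0L,
    degenerate = degenerate
  ), class = "dde_binary_metrics")
}

# trapezoidal area under y(x) with x ascending
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' ROC curve and AUC
#'
#' Operating points at every distinct score (ties stepped together), with
#' (0,0) and (1,1) anchors; AUC by trapezoidal integration, which with the
#' tie-grouped construction equals the pairwise concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie). Undefined (AUC `NA`) when the
#' gold labels are single-class.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param gold Aligned 0/1 labels.
#' @return List of class `dde_curve`: `points` tibble (`x` = FPR, `y` = TPR,
#'   ascending x), `auc`, `defined`, `type = "roc"`.
#' @export
roc_curve <- function(scores, gold) {
  stopifnot(length(scores) == length(gold))
  pos <- sum(gold == 1L); neg <- sum(gold == 0L)
  if (pos == 0L || neg == 0L) {
    return(structure(list(points = tibble::tibble(x = numeric(), y = numeric()),
                          auc = NA_real_, defined = FALSE, type = "roc"),
                     class = "dde_curve"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; g <- gold[ord]
  # indices of the last element of each tie group, in descending-score order
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(g == 1L)[last]
  fp <- cumsum(g == 0L)[last]
  x <- c(0, fp / neg)
  y <- c(0, tp / pos)
  structure(list(
    points = tibble::tibble(x = x, y = y),
    auc = trapezoid_area(x, y),
    defined = TRUE, type = "roc"
  ), class = "dde_curve")
}

#' Precision–recall curve and AUC
#'
#' Operating points at every distinct score threshold (items scoring at or
#' above the threshold are predicted positive), ordered by ascending recall
#' with the right endpoint at recall 1; the curve is extended horizontally
#' to recall 0 and integrated by trapezoid over recall. Undefined when
#' there are no gold positives.
#'
#' @inheritParams roc_curve
#' @return List of class `dde_curve`: `points` tibble (`x` = recall,
#'   `y` = precision), `auc`, `defined`, `type = "pr"`.
#' @export
pr_curve <- function(scores, gold) {
  stopifnot(length(scores) == length(gold))
  pos <- sum(gold == 1L)
  if (pos == 0L) {
    return(structure(list(points = tibble::tibble(x = numeric(), y = numeric()),
                          auc = NA_real_, defined = FALSE, type = "pr"),
                     class = "dde_curve"))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; g <- gold[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(g == 1L)[last]
  n_pred <- last
  recall <- tp / pos
  precision <- tp / n_pred
  x <- c(0, recall)
  y <- c(precision[1], precision)
  structure(list(
    points = tibble::tibble(x = x, y = y),
    auc = trapezoid_area(x, y),
    defined = TRUE, type = "pr"
  ), class = "dde_curve")
}

# membership matrix (items x categories) from a list of category vectors;
# rows with NA (missing predictions) are left NA throughout
membership_matrix <- function(sets, categories) {
  m <- matrix(0L, nrow = length(sets), ncol = length(categories),
              dimnames = list(NULL, categories))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) == 1L && is.na(s)) {
      m[i, ] <- NA_integer_
    } else {
      bad <- setdiff(s, categories)
      if (length(bad) > 0L) {
        stop("categories outside the taxonomy: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      m[i, match(s, categories)] <- 1L
    }
  }
  m
}

align_sets <- function(pred, gold) {
  orphan_pred <- setdiff(pred$comment_id, gold$comment_id)
  orphan_gold <- setdiff(gold$comment_id, pred$comment_id)
  if (length(orphan_pred) + length(orphan_gold) > 0L) {
    stop("prediction/gold id mismatch; unmatched predictions: [",
         paste(orphan_pred, collapse = ", "), "], unmatched gold: [",
         paste(orphan_gold, collapse = ", "), "]", call. = FALSE)
  }
  pred[match(gold$comment_id, pred$comment_id), ]
}

#' Multilabel hamming loss
#'
#' Fraction of item-by-category membership cells predicted incorrectly.
#'
#' @param pred,gold Tibbles with `comment_id` and list-column `categories`.
#' @param categories The closed label set; defaults to the 8-category
#'   taxonomy.
#' @return Value in \[0, 1\].
#' @export
hamming_loss <- function(pred, gold, categories = rootcause_categories()) {
  pred <- align_sets(pred, gold)
  pm <- membership_matrix(pred$categories, categories)
  gm <- membership_matrix(gold$categories, categories)
  keep <- !is.na(pm[, 1])
  mean(pm[keep, , drop = FALSE] != gm[keep, , drop = FALSE])
}

#' Sample-averaged Jaccard score and subset accuracy
#'
#' Per-item Jaccard is |pred n gold| / |pred u gold| with the empty/empty
#' case defined as 1; subset accuracy is the fraction of items whose
#' predicted set equals the gold set exactly. Subset accuracy never exceeds
#' the sample-averaged Jaccard.
#'
#' @inheritParams hamming_loss
#' @return List with `jaccard`, `subset_accuracy`, `excluded`.
#' @export
jaccard_and_subset <- function(pred, gold,
                               categories = rootcause_categories()) {
  pred <- align_sets(pred, gold)
  missing <- vapply(pred$categories, function(s) {
    length(s) == 1L && is.na(s)
  }, logical(1))
  p <- pred$categories[!missing]
  g <- gold$categories[!missing]
  jac <- mapply(function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 1 else length(intersect(a, b)) / u
  }, p, g)
  exact <- mapply(function(a, b) setequal(a, b), p, g)
  list(jaccard = mean(jac), subset_accuracy = mean(exact),
       excluded = sum(missing))
}

#' Full multilabel evaluation report
#'
#' Everything reported for the root-cause task: per-category confusion
#' rates; micro (cells pooled across categories), macro (unweighted mean),
#' and weighted (gold-support-weighted mean) F1; hamming loss, sample
#' Jaccard, subset accuracy; and, when per-category scores are available
#' (CS1/CS2), micro/macro/weighted ROC and PR AUCs. Score-free predictions
#' (CS3) leave the AUC fields `NA` and flagged undefined. Categories whose
#' gold column is single-class have undefined per-category AUC and are
#' excluded from the macro/weighted AUC means (count reported).
#'
#' @param pred Predictions tibble with `comment_id`, list-column
#'   `categories`, and optionally list-column `per_category_scores` (named
#'   numeric vectors over all categories).
#' @param gold Gold tibble with `comment_id` and list-column `categories`.
#' @inheritParams hamming_loss
#' @return List of class `dde_multilabel_report`.
#' @export
multilabel_report <- function(pred, gold,
                              categories = rootcause_categories()) {
  pred <- align_sets(pred, gold)
  missing <- vapply(pred$categories, function(s) {
    length(s) == 1L && is.na(s)
  }, logical(1))
  pm <- membership_matrix(pred$categories[!missing], categories)
  gm <- membership_matrix(gold$categories[!missing], categories)
  per_class <- dplyr::bind_rows(lapply(categories, function(cat) {
    cm <- confusion_from_labels(pm[, cat], gm[, cat])
    m <- binary_metrics(cm)
    tibble::tibble(
      category = cat, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      support = cm$tp + cm$fn, precision = m$precision, recall = m$recall,
      f1 = m$f1, accuracy = m$accuracy, fpr = m$fpr, tpr = m$tpr,
      fnr = m$fnr, tnr = m$tnr
    )
  }))
  micro <- binary_metrics(confusion_matrix(
    sum(per_class$tp), sum(per_class$fp), sum(per_class$fn),
    sum(per_class$tn)
  ))
  w <- per_class$support / sum(per_class$support)
  js <- jaccard_and_subset(tibble::tibble(comment_id = gold$comment_id,
                                          categories = pred$categories),
                           gold, categories)
  scores_avail <- "per_category_scores" %in% names(pred) &&
    all(vapply(pred$per_category_scores[!missing], length, integer(1)) ==
          length(categories))
  aucs <- list(micro_roc_auc = NA_real_, macro_roc_auc = NA_real_,
               weighted_roc_auc = NA_real_, micro_pr_auc = NA_real_,
               macro_pr_auc = NA_real_, weighted_pr_auc = NA_real_,
               auc_defined = FALSE, n_undefined_class_auc = NA_integer_)
  per_class$roc_auc <- NA_real_
  per_class$pr_auc <- NA_real_
  if (scores_avail) {
    sm <- do.call(rbind, lapply(pred$per_category_scores[!missing],
                                function(s) s[categories]))
    per_class$roc_auc <- vapply(categories, function(cat) {
      roc_curve(sm[, cat], gm[, cat])$auc
    }, numeric(1))
    per_class$pr_auc <- vapply(categories, function(cat) {
      pr_curve(sm[, cat], gm[, cat])$auc
    }, numeric(1))
    def <- !is.na(per_class$roc_auc)
    wd <- per_class$support[def] / sum(per_class$support[def])
    aucs <- list(
      micro_roc_auc = roc_curve(as.vector(sm), as.vector(gm))$auc,
      macro_roc_auc = mean(per_class$roc_auc[def]),
      weighted_roc_auc = sum(wd * per_class$roc_auc[def]),
      micro_pr_auc = pr_curve(as.vector(sm), as.vector(gm))$auc,
      macro_pr_auc = mean(per_class$pr_auc[def], na.rm = TRUE),
      weighted_pr_auc = sum(wd * per_class$pr_auc[def]),
      auc_defined = TRUE,
      n_undefined_class_auc = sum(!def)
    )
  }
  structure(c(list(
    micro_f1 = micro$f1,
    macro_f1 = mean(per_class$f1),
    weighted_f1 = sum(w * per_class$f1),
    micro_precision = micro$precision,
    micro_recall = micro$recall,
    hamming_loss = mean(pm != gm),
    jaccard = js$jaccard,
    subset_accuracy = js$subset_accuracy,
    excluded = sum(missing),
    per_class = list(per_class)
  ), aucs), class = "dde_multilabel_report")
}

#' Class prevalence summary for binary gold labels
#'
#' @param gold 0/1 vector of consensus labels.
#' @return Tibble with `class`, `n`, `percent` (rounded half-up, 1 decimal).
#' @export
dataset_summary <- function(gold) {
  if (length(gold) == 0L) stop("no gold labels supplied", call. = FALSE)
  counts <- table(factor(gold, levels = c(0L, 1L)))
  tibble::tibble(
    class = c("non_dde", "dde"),
    n = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / length(gold), 1)
  )
}

#' Category frequency table for root-cause gold sets
#'
#' How often each taxonomy category occurs across annotated comments;
#' percentages are of comments (multilabel, so they exceed 100 in total).
#'
#' @param gold Tibble with list-column `categories`.
#' @inheritParams hamming_loss
#' @return Tibble with `category`, `n`, `percent` (1 decimal, half-up).
#' @export
rootcause_frequency <- function(gold, categories = rootcause_categories()) {
  if (nrow(gold) == 0L) stop("no gold sets supplied", call. = FALSE)
  m <- membership_matrix(gold$categories, categories)
  n <- colSums(m)
  tibble::tibble(
    category = categories,
    n = as.integer(n),
    percent = round_half_up(100 * n / nrow(gold), 1)
  )
}
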