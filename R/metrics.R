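# Multi-class diagnostic metrics: confusion matrix, per-class and macro
# precision/recall/F1 (percent scale, printed at one decimal), and
# one-vs-rest AUC-ROC (midrank construction) and AUC-PR (conservative step
# interpolation).

#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors (factors, characters or integer codes
#'   `1..K`); sample order is irrelevant.
#' @param k Number of classes; inferred from factor levels when omitted.
#' @param levels Optional class labels for the dimnames.
#' @return A `K x K` integer matrix; entry `(i, j)` counts true class `i`
#'   predicted as class `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, k = NULL, levels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` lengths differ")
  }
  if (is.null(levels)) {
    if (is.factor(y_true)) {
      levels <- base::levels(y_true)
    } else if (is.character(y_true) || is.character(y_pred)) {
      levels <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    }
  }
  if (!is.null(levels)) {
    ti <- as.integer(factor(as.character(y_true), levels = levels))
    pi <- as.integer(factor(as.character(y_pred), levels = levels))
    k <- length(levels)
  } else {
    ti <- as.integer(y_true)
    pi <- as.integer(y_pred)
    k <- k %||% max(ti, pi)
  }
  if (any(is.na(ti)) || any(is.na(pi)) || any(ti < 1) || any(pi < 1) ||
      any(ti > k) || any(pi > k)) {
    stop("labels outside 1..K")
  }
  cm <- matrix(0L, k, k)
  for (s in seq_along(ti)) cm[ti[s], pi[s]] <- cm[ti[s], pi[s]] + 1L
  if (!is.null(levels)) dimnames(cm) <- list(true = levels, predicted = levels)
  cm
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`, on whatever scale (fraction or
#' percent) the inputs share; 0 when both are 0.
#'
#' @param precision,recall Numeric vectors.
#' @return F1 values on the same scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 their
#' harmonic mean.  Classes never predicted (`TP+FP = 0`) contribute
#' precision 0 with a message.  Macro averaging (unweighted class mean) is
#' the default; weighted averaging uses class support.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param averaging `"macro"`, `"weighted"` or `"per_class"`.
#' @return For the averaged modes, a named vector `c(precision, recall,
#'   f1)` in percent; for `"per_class"` a data frame with one row per class.
#' @export
precision_recall_f1 <- function(cm, averaging = c("macro", "weighted", "per_class")) {
  averaging <- match.arg(averaging)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("`cm` must be a non-empty square confusion matrix")
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom_p <- tp + fp
  if (any(denom_p == 0)) {
    message(sum(denom_p == 0), " class(es) never predicted; precision set to 0")
  }
  precision <- ifelse(denom_p == 0, 0, tp / denom_p) * 100
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn)) * 100
  f1 <- f1_score(precision, recall)
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    support = rowSums(cm), precision = precision, recall = recall, f1 = f1,
    row.names = NULL
  )
  switch(averaging,
    per_class = per_class,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = {
      w <- rowSums(cm) / sum(cm)
      c(precision = sum(w * precision), recall = sum(w * recall),
        f1 = sum(w * f1))
    }
  )
}

binary_auc_roc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest macro AUC-ROC
#'
#' Per-class AUC via the rank (Mann-Whitney) construction with midrank tie
#' handling, macro-averaged over classes that have at least one positive
#' and one negative sample (others are skipped with a warning).
#'
#' @param scores `n x K` matrix of class scores/probabilities.
#' @param y_true Labels (factor or integer codes aligned with the columns).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, y_true) {
  scores <- as.matrix(scores)
  yi <- if (is.factor(y_true)) as.integer(y_true) else as.integer(y_true)
  if (length(unique(yi)) < 2) stop("labels contain a single class")
  aucs <- numeric(0)
  skipped <- 0
  for (k in seq_len(ncol(scores))) {
    pos <- yi == k
    if (!any(pos) || all(pos)) {
      skipped <- skipped + 1
      next
    }
    aucs <- c(aucs, binary_auc_roc(scores[, k], pos))
  }
  if (skipped > 0) {
    warning(skipped, " class(es) without both positives and negatives skipped")
  }
  mean(aucs)
}

binary_auc_pr <- function(scores, positive) {
  n_pos <- sum(positive)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  p_sorted <- positive[ord]
  cum_tp <- cumsum(p_sorted)
  cum_n <- seq_along(p_sorted)
  # operating point at each distinct threshold = last index with that score
  last_idx <- cumsum(rle(s_sorted)$lengths)
  tp <- cum_tp[last_idx]
  n_at <- cum_n[last_idx]
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' One-vs-rest macro AUC-PR
#'
#' Per-class area under the precision-recall step curve with conservative
#' (non-linear) interpolation: `sum(delta recall * precision)` over the
#' distinct score thresholds, macro-averaged over classes with at least one
#' positive.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(scores, y_true) {
  scores <- as.matrix(scores)
  yi <- if (is.factor(y_true)) as.integer(y_true) else as.integer(y_true)
  if (!length(yi) || all(tabulate(yi, ncol(scores)) == 0)) {
    stop("no positive samples for any class")
  }
  aucs <- numeric(0)
  for (k in seq_len(ncol(scores))) {
    pos <- yi == k
    if (!any(pos)) next
    aucs <- c(aucs, binary_auc_pr(scores[, k], pos))
  }
  mean(aucs)
}

#' Full metrics report
#'
#' Bundles the confusion matrix, accuracy, per-class and macro
#' precision/recall/F1 (percent) and, when scores are supplied, one-vs-rest
#' macro AUC-ROC and AUC-PR.
#'
#' @param y_true,y_pred Label vectors.
#' @param scores Optional `n x K` probability/score matrix.
#' @param levels Optional class labels.
#' @return An object of class `"metrics_report"`; printed at one decimal on
#'   the percent scale.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, levels = NULL) {
  cm <- confusion_matrix(y_true, y_pred, levels = levels)
  macro <- precision_recall_f1(cm, "macro")
  rep <- list(
    confusion = cm,
    accuracy = 100 * sum(diag(cm)) / sum(cm),
    precision = macro[["precision"]],
    recall = macro[["recall"]],
    f1 = macro[["f1"]],
    per_class = precision_recall_f1(cm, "per_class"),
    auc_roc = NA_real_, auc_pr = NA_real_
  )
  if (!is.null(scores)) {
    rep$auc_roc <- tryCatch(suppressWarnings(auc_roc(scores, y_true)),
                            error = function(e) NA_real_)
    rep$auc_pr <- tryCatch(suppressWarnings(auc_pr(scores, y_true)),
                           error = function(e) NA_real_)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Accuracy:  ", round(x$accuracy, 1), "%\n", sep = "")
  cat("Macro precision/recall/F1: ",
      round(x$precision, 1), " / ", round(x$recall, 1), " / ",
      round(x$f1, 1), " %\n", sep = "")
  if (!is.na(x$auc_roc)) {
    cat("AUC-ROC: ", round(x$auc_roc, 3),
        "  AUC-PR: ", round(x$auc_pr, 3), "\n", sep = "")
  }
  cat("\nConfusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
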