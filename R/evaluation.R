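# Deterministic ranking order: score descending, then lexicographic
# (regulator, target) when pair names are supplied, else input order.
ranking_order <- function(scores, pairs = NULL) {
  if (is.null(pairs)) {
    order(-scores, seq_along(scores), method = "radix")
  } else {
    order(-scores, pairs[, 1L], pairs[, 2L], method = "radix")
  }
}

#' Confusion counts among the top-k ranked pairs
#'
#' The k highest-scored candidates are called positive (ties broken by the
#' global deterministic rule), everything else negative. Recall uses all
#' positives in the evaluated set as denominator.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param k Number of top predictions to call positive.
#' @param pairs Optional character matrix of (regulator, target) names used
#'   for deterministic tie-breaking.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_at_topk <- function(scores, labels, k, pairs = NULL) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k > length(scores)) stop("k exceeds number of scored pairs",
                               call. = FALSE)
  ord <- ranking_order(scores, pairs)
  top <- ord[seq_len(k)]
  tp <- sum(labels[top] == 1)
  fp <- k - tp
  fn <- sum(labels == 1) - tp
  tn <- sum(labels == 0) - fp
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' ROC AUC via the rank statistic
#'
#' Equals the probability that a random positive outranks a random negative,
#' with ties counted as one half (Mann-Whitney formulation).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: both classes required", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: the sum over positives
#' in rank order of precision-at-rank times the recall increment.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with at least one positive.
#' @param pairs Optional pair names for deterministic tie-breaking.
#' @return AUPR in `(0, 1]`.
#' @export
average_precision <- function(scores, labels, pairs = NULL) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0L) stop("AUPR undefined: no positives", call. = FALSE)
  ord <- ranking_order(scores, pairs)
  lab <- labels[ord]
  cum_tp <- cumsum(lab == 1)
  prec <- cum_tp / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

prf_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Full ranking-metrics report
#'
#' Assembles confusion counts at the score-zero decision threshold, AUC,
#' AUPR (average precision) and a per-k table of precision/recall/F1 for the
#' requested k values (defaults 10, 50, 100; values exceeding the number of
#' scored pairs are dropped with a warning).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param ks Integer vector of k values.
#' @param pairs Optional pair names for deterministic tie-breaking.
#' @return Object of class `MetricsReport`.
#' @export
full_report <- function(scores, labels, ks = c(10L, 50L, 100L),
                        pairs = NULL) {
  stopifnot(length(scores) == length(labels))
  keep <- ks <= length(scores)
  if (!all(keep)) {
    warning("dropping k values exceeding the number of scored pairs")
    ks <- ks[keep]
  }
  pred_pos <- scores > 0
  tp <- sum(pred_pos & labels == 1)
  fp <- sum(pred_pos & labels == 0)
  fn <- sum(!pred_pos & labels == 1)
  tn <- sum(!pred_pos & labels == 0)
  prf <- prf_from_counts(tp, fp, fn)
  topk <- do.call(rbind, lapply(ks, function(k) {
    cm <- confusion_at_topk(scores, labels, k, pairs)
    pr <- prf_from_counts(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    data.frame(k = k, TP = cm[["TP"]], FP = cm[["FP"]], TN = cm[["TN"]],
               FN = cm[["FN"]], precision = pr[["precision"]],
               recall = pr[["recall"]], f1 = pr[["f1"]])
  }))
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    TPR = if (tp + fn == 0) 0 else tp / (tp + fn),
    FPR = if (fp + tn == 0) 0 else fp / (fp + tn),
    precision = prf[["precision"]], recall = prf[["recall"]],
    f1 = prf[["f1"]],
    auc = roc_auc(scores, labels),
    aupr = average_precision(scores, labels, pairs),
    aupr_rule = "average precision (no interpolation)",
    topk = topk,
    n = length(scores), n_pos = sum(labels == 1)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: %d pairs (%d positives)\n", x$n, x$n_pos))
  cat(sprintf("  AUC %.4f  AUPR %.4f [%s]\n", x$auc, x$aupr, x$aupr_rule))
  for (i in seq_len(nrow(x$topk))) {
    r <- x$topk[i, ]
    cat(sprintf("  P@%-4d %.4f  R@%-4d %.4f  F1@%-4d %.4f\n",
                r$k, r$precision, r$k, r$recall, r$k, r$f1))
  }
  invisible(x)
}

#' Flatten a metrics report into the standard report row
#'
#' Columns ordered AUC, AUPR, Precision@k, Recall@k, F1@k for the largest
#' requested k (100 by default when available).
#'
#' @param x A `MetricsReport`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  k <- max(x$topk$k)
  r <- x$topk[x$topk$k == k, ]
  out <- data.frame(AUC = x$auc, AUPR = x$aupr, precision_at_k = r$precision,
                    recall_at_k = r$recall, f1_at_k = r$f1, k = k)
  if (!is.null(row.names)) rownames(out) <- row.names
  out
}

#' Export a metrics report
#'
#' @param x A `MetricsReport`.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @export
write_metrics_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
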