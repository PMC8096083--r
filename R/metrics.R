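#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) with midrank tie handling: the probability
#' that a random positive scores above a random negative.
#'
#' @param scores numeric ranking scores (higher = more positive)
#' @param labels 0/1 labels
#' @return AUROC in \[0, 1\]
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes to compute AUROC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (MAP) with step interpolation
#'
#' Mean of the precision at each positive item when items are ranked by
#' decreasing score — the step-function area under the precision-recall
#' relationship.
#'
#' @inheritParams auroc
#' @return average precision in \[0, 1\]
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L) stop("need positive items to compute MAP")
  ord <- order(-scores)
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  mean(prec_at[y == 1L])
}

#' Area under the precision-recall curve (trapezoidal)
#'
#' Precision-recall points are taken at every rank cutoff of the
#' score-ordered list (prepending recall 0 at the first point's precision)
#' and integrated with the trapezoid rule over recall. The trapezoidal
#' convention makes this deliberately distinct from the step-interpolated
#' [average_precision()].
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("need positive items to compute AUPRC")
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / n_pos
  rec <- c(0, rec)
  prec <- c(prec[1L], prec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Precision, recall and F1 at a decision threshold
#'
#' Per-class precision/recall/F1 at the hard decision `score >= threshold`,
#' averaged either `"macro"` (unweighted mean over the two classes, the
#' default) or `"micro"` (pooled counts; equals accuracy for binary
#' single-label decisions). F1 is the harmonic mean of the per-class P and R
#' before averaging.
#'
#' @inheritParams auroc
#' @param threshold decision threshold on the scores
#' @param average `"macro"` or `"micro"`
#' @return named numeric vector `precision`, `recall`, `f1`
#' @export
precision_recall_f1 <- function(scores, labels, threshold = 0.5,
                                average = c("macro", "micro")) {
  average <- match.arg(average)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  per_class <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f, tp = tp, fp = fp, fn = fn)
  }
  if (average == "macro") {
    m <- (per_class(0L) + per_class(1L)) / 2
    c(precision = unname(m["p"]), recall = unname(m["r"]), f1 = unname(m["f"]))
  } else {
    a <- per_class(0L); b <- per_class(1L)
    tp <- a["tp"] + b["tp"]; fp <- a["fp"] + b["fp"]; fn <- a["fn"] + b["fn"]
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    c(precision = unname(p), recall = unname(r),
      f1 = unname(2 * p * r / (p + r)))
  }
}

#' Full metrics report for scored edges
#'
#' The six evaluation metrics: precision, recall and F1 at a hard decision
#' threshold, plus the threshold-free ranking metrics MAP (step-interpolated
#' average precision), AUROC, and AUPRC (trapezoidal).
#'
#' @inheritParams precision_recall_f1
#' @return a `metrics_report`: named numeric vector with entries `precision`,
#'   `recall`, `f1`, `map`, `auroc`, `auprc`, all in \[0, 1\]
#' @export
metrics_report <- function(scores, labels, threshold = 0.5,
                           average = c("macro", "micro")) {
  average <- match.arg(average)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("test set must contain both classes")
  prf <- precision_recall_f1(scores, labels, threshold, average)
  out <- c(prf,
           map = average_precision(scores, labels),
           auroc = auroc(scores, labels),
           auprc = auprc(scores, labels))
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unclass(x)
  cat(paste(sprintf("%s=%.2f%%", names(v), 100 * v), collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a trained edge classifier on a test split
#'
#' @param classifier an [train_edge_classifier()] result
#' @param x_test feature matrix
#' @param y_test 0/1 labels containing both classes
#' @param average P/R/F1 averaging convention (see [precision_recall_f1()])
#' @return a [metrics_report()]
#' @export
evaluate_classifier <- function(classifier, x_test, y_test,
                                average = c("macro", "micro")) {
  scores <- predict(classifier, x_test, type = "prob")
  metrics_report(scores, y_test, threshold = 0.5, average = match.arg(average))
}

#' Two-sided t-test over repeated-run scores
#'
#' Compares the per-run scores of two approaches (e.g., ten seeded runs each)
#' with a two-sided two-sample t-test.
#'
#' @param scores_a,scores_b numeric vectors of per-run scores (length >= 2)
#' @param var_equal assume equal variances (classical two-sample test);
#'   defaults to `TRUE`
#' @return the two-sided p-value
#' @export
repeated_runs_ttest <- function(scores_a, scores_b, var_equal = TRUE) {
  stopifnot(length(scores_a) >= 2L, length(scores_b) >= 2L)
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0) {
    stop("zero variance in both samples: t-test undefined")
  }
  stats::t.test(scores_a, scores_b, alternative = "two.sided",
                var.equal = var_equal)$p.value
}
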