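#' Confusion-count classification metrics
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction)
#' and derives accuracy `(tp + tn) / (tp + fp + fn + tn)` (for K > 2,
#' micro accuracy = trace/total), per-class one-vs-rest recall
#' `tp / (tp + fn)`, precision `tp / (tp + fp)`, and
#' `f1 = 2 * Prec * Rec / (Prec + Rec)`, plus the macro-averaged f1. A
#' metric with a zero denominator is reported as 0 and flagged in
#' `degenerate`. For binary tasks the positive class is the highest label
#' (the "abnormal" class), and its recall/precision/f1 are surfaced as
#' `recall_pos`, `precision_pos`, `f1_pos`.
#'
#' @param truth,predicted Integer vectors of labels in `1..n_classes`.
#' @param n_classes Number of classes K (default: max observed label).
#' @return An object of class `ddx_eval` with fields `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1` (per class), `macro_f1`,
#'   `degenerate` (logical per class), and for K = 2 the positive-class
#'   fields.
#' @export
confusion_metrics <- function(truth, predicted, n_classes = NULL) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(truth, predicted)
  K <- as.integer(n_classes)
  if (any(truth < 1L | truth > K) || any(predicted < 1L | predicted > K))
    stop(sprintf("labels must lie in 1..%d", K), call. = FALSE)
  conf <- table(factor(truth, levels = seq_len(K)),
                factor(predicted, levels = seq_len(K)))
  conf <- matrix(as.integer(conf), K, K,
                 dimnames = list(truth = seq_len(K), predicted = seq_len(K)))
  n <- length(truth)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  rec <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  degenerate <- (tp + fn) == 0 | (tp + fp) == 0 | (prec + rec) == 0
  out <- list(confusion = conf, accuracy = sum(tp) / n,
              precision = prec, recall = rec, f1 = f1,
              macro_f1 = mean(f1), degenerate = degenerate, n = n)
  if (K == 2L) {
    out$recall_pos <- unname(rec[2L])
    out$precision_pos <- unname(prec[2L])
    out$f1_pos <- unname(f1[2L])
  }
  structure(out, class = "ddx_eval")
}

#' @export
print.ddx_eval <- function(x, ...) {
  cat(sprintf("ddx_eval: n = %d, accuracy = %.4f, macro f1 = %.4f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

# AUROC of one score/label column via the rank statistic (ties averaged)
auroc_column <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve, pooled or aggregated over labels
#'
#' Computed exactly via the rank (Mann-Whitney) statistic with ties
#' averaged, equal to the probability that a random positive outscores a
#' random negative (ties counting one half). For multilabel matrices:
#' `micro` pools all (sample, label) pairs; `macro` is the unweighted mean
#' of per-label AUROCs; `weighted` weights each label by its prevalence
#' among positives. Label columns lacking both a positive and a negative
#' are excluded from macro/weighted aggregation with a warning.
#'
#' @param scores Numeric vector `[N]` or matrix `[N, L]`.
#' @param labels 0/1 vector or matrix of the same shape.
#' @param mode One of `"micro"`, `"macro"`, `"weighted"`; ignored for
#'   vector input.
#' @return Scalar AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels, mode = c("micro", "macro", "weighted")) {
  mode <- match.arg(mode)
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1L)
    labels <- matrix(labels, ncol = 1L)
    mode <- "micro"
  }
  if (!all(dim(scores) == dim(labels)))
    stop("'scores' and 'labels' must have the same shape", call. = FALSE)
  if (any(labels != 0 & labels != 1)) stop("'labels' must be 0/1", call. = FALSE)
  if (mode == "micro") {
    s <- as.numeric(scores); y <- as.numeric(labels)
    if (all(y == 1) || all(y == 0))
      stop("pooled labels are all one class; AUROC undefined", call. = FALSE)
    return(auroc_column(s, y))
  }
  per <- vapply(seq_len(ncol(scores)),
                function(j) auroc_column(scores[, j], labels[, j]), numeric(1))
  ok <- !is.na(per)
  if (!any(ok))
    stop("every label column is degenerate; AUROC undefined", call. = FALSE)
  if (any(!ok))
    warning(sprintf("%d degenerate label column(s) excluded", sum(!ok)),
            call. = FALSE)
  if (mode == "macro") return(mean(per[ok]))
  wts <- colSums(labels)[ok]
  sum(per[ok] * wts) / sum(wts)
}
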