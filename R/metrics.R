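# Thresholded and threshold-free evaluation of per-residue predictions.

#' Evaluate per-residue predictions
#'
#' Confusion counts at `score >= threshold` (positive call), the five
#' formula metrics (ACC, precision, recall, F1, MCC), AUROC by the
#' Mann-Whitney rank statistic (ties count one half), and AUPRC by
#' step-wise precision-recall integration (no trapezoidal interpolation,
#' which is optimistic on PR curves).
#'
#' Degenerate confusion tables are guarded rather than propagated as
#' `NaN`: a metric whose defining denominator is zero is reported as 0
#' (AUROC/AUPRC as `NA` when a class is absent) and its name is listed in
#' the `degenerate` field.
#'
#' @param labels 0/1 vector of true classes.
#' @param scores Numeric vector of predicted scores in (0, 1).
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (!length(labels)) stop("cannot compute metrics on empty input")
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  P <- tp + fn
  Neg <- tn + fp
  degenerate <- character(0)
  acc <- (tp + tn) / n
  precision <- if (tp + fp == 0) {
    degenerate <- c(degenerate, "precision"); 0
  } else tp / (tp + fp)
  recall <- if (P == 0) {
    degenerate <- c(degenerate, "recall"); 0
  } else tp / P
  f1 <- if (2 * tp + fp + fn == 0) {
    degenerate <- c(degenerate, "f1"); 0
  } else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn)) *
    sqrt(as.numeric(tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc"); 0
  } else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  if (P == 0 || Neg == 0) {
    degenerate <- c(degenerate, "auroc", "auprc")
    auroc <- NA_real_
    auprc <- NA_real_
  } else {
    r <- rank(scores, ties.method = "average")
    auroc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (as.numeric(P) * Neg)
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord]
    s <- scores[ord]
    ctp <- cumsum(y)
    cfp <- cumsum(1L - y)
    last_of_group <- c(s[-1] != s[-n], TRUE)
    tpk <- ctp[last_of_group]
    fpk <- cfp[last_of_group]
    prec_k <- tpk / (tpk + fpk)
    rec_k <- tpk / P
    auprc <- sum(diff(c(0, rec_k)) * prec_k)
  }
  structure(list(acc = acc, precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, auroc = auroc, auprc = auprc,
                 threshold = threshold,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 n = n, degenerate = unique(degenerate)),
            class = "metrics_report")
}

#' Pick the threshold maximizing F1 on held-out scores
#'
#' The published evaluation does not state how its operating threshold was
#' chosen; this provides the F1-maximizing alternative to the 0.5 default.
#' Candidate thresholds are the observed score values.
#'
#' @inheritParams compute_metrics
#' @return The score value maximizing F1 (ties broken toward the larger
#'   threshold).
#' @export
best_f1_threshold <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  cand <- sort(unique(scores), decreasing = TRUE)
  f1s <- vapply(cand, function(t) compute_metrics(labels, scores, t)$f1, 0)
  cand[[which.max(f1s)]]
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics @ threshold %.3g (n = %d): ACC %.3f  P %.3f  R %.3f  F1 %.3f  MCC %.3f  AUROC %s  AUPRC %s\n",
    x$threshold, x$n, x$acc, x$precision, x$recall, x$f1, x$mcc,
    ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
    ifelse(is.na(x$auprc), "NA", sprintf("%.3f", x$auprc))))
  if (length(x$degenerate))
    cat(" degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(acc = x$acc, precision = x$precision, recall = x$recall,
             f1 = x$f1, mcc = x$mcc, auroc = x$auroc, auprc = x$auprc,
             threshold = x$threshold,
             tp = x$counts[["tp"]], tn = x$counts[["tn"]],
             fp = x$counts[["fp"]], fn = x$counts[["fn"]])
}
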