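# Accuracy evaluation: junction matching, confusion counts
# (sensitivity/precision/F1), threshold-swept precision-recall curves with
# trapezoidal AUC, and truth-free false-positive summaries.

#' Match predictions against a truth junction set
#'
#' A prediction matches iff some truth junction on the same chromosome (and
#' strand, in strict mode) has |delta start| <= tolerance and
#' |delta end| <= tolerance. A truth junction may satisfy many predictions,
#' but each prediction matches at most once.
#'
#' @param preds data.frame with chrom, start, end (and strand).
#' @param truth data.frame with chrom, start, end (and strand).
#' @param tolerance_bp coordinate slack in bp (default 0: exact junctions).
#' @param strict_strand require strand agreement.
#' @return logical vector along the rows of `preds`.
#' @export
match_predictions <- function(preds, truth, tolerance_bp = 0L,
                              strict_strand = FALSE) {
  if (nrow(preds) == 0) return(logical(0))
  if (nrow(truth) == 0) return(rep(FALSE, nrow(preds)))
  if (tolerance_bp == 0) {
    pk <- junction_key(preds$chrom, preds$start, preds$end, preds$strand, strict_strand)
    tk <- junction_key(truth$chrom, truth$start, truth$end, truth$strand, strict_strand)
    return(pk %in% tk)
  }
  by_chrom <- split(truth, truth$chrom)
  vapply(seq_len(nrow(preds)), function(i) {
    tt <- by_chrom[[preds$chrom[i]]]
    if (is.null(tt)) return(FALSE)
    if (strict_strand) tt <- tt[tt$strand == preds$strand[i], , drop = FALSE]
    any(abs(tt$start - preds$start[i]) <= tolerance_bp &
        abs(tt$end - preds$end[i]) <= tolerance_bp)
  }, logical(1))
}

#' Confusion counts from raw integers
#'
#' Sensitivity S = TP / truth size, precision P = TP / detected,
#' F1 = 2PS / (P + S). Metrics are held at full precision; [print] and
#' [summary] round to two decimals (percent scale for S and P). Undefined
#' quantities (empty truth, zero detections) are NA.
#'
#' @param n_detected predictions passing the support filter.
#' @param n_tp detected predictions matching a truth junction.
#' @param n_truth truth set size.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_detected, n_tp, n_truth) {
  stopifnot(n_tp >= 0, n_tp <= n_detected, n_detected >= 0, n_truth >= 0)
  if (n_truth > 0 && n_tp > n_truth) stop("n_tp exceeds truth size")
  S <- if (n_truth > 0) n_tp / n_truth else NA_real_
  P <- if (n_detected > 0) n_tp / n_detected else NA_real_
  f1 <- if (is.na(S) || is.na(P)) NA_real_
        else if (P + S == 0) 0 else 2 * P * S / (P + S)
  structure(list(n_truth = as.integer(n_truth),
                 n_detected = as.integer(n_detected), n_tp = as.integer(n_tp),
                 sensitivity = S, precision = P, f1 = f1),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("detected %d, TP %d, truth %d | S %% = %s, P %% = %s, F1 = %s\n",
              x$n_detected, x$n_tp, x$n_truth,
              ifelse(is.na(s$sensitivity_pct), "-", sprintf("%.2f", s$sensitivity_pct)),
              ifelse(is.na(s$precision_pct), "-", sprintf("%.2f", s$precision_pct)),
              ifelse(is.na(s$f1), "-", sprintf("%.2f", s$f1))))
  invisible(x)
}

#' @export
summary.confusion_counts <- function(object, ...) {
  list(n_truth = object$n_truth, n_detected = object$n_detected,
       n_tp = object$n_tp,
       sensitivity_pct = round(100 * object$sensitivity, 2),
       precision_pct = round(100 * object$precision, 2),
       f1 = round(object$f1, 2))
}

#' Evaluate predictions against truth
#'
#' Filters predictions at a minimum junction-read support (default 2),
#' matches them to truth junctions and returns confusion counts.
#'
#' @param preds prediction data.frame (chrom, start, end, strand, support).
#' @param truth truth data.frame (chrom, start, end, strand); may be empty.
#' @param min_support support filter (predictions with support >= this count).
#' @param tolerance matching slack in bp.
#' @param strict_strand require strand agreement when matching.
#' @return object of class `confusion_counts`.
#' @export
confusion <- function(preds, truth, min_support = 2L, tolerance = 0L,
                      strict_strand = FALSE) {
  det <- preds[preds$support >= min_support, , drop = FALSE]
  n_tp <- sum(match_predictions(det, truth, tolerance, strict_strand))
  confusion_counts(nrow(det), n_tp, nrow(truth))
}

#' Threshold-swept precision-recall curve and AUC
#'
#' For each integer threshold t from 1 to the maximum observed support,
#' predictions with support >= t are scored; AUC is the trapezoidal integral
#' of precision over recall after sorting points by recall ascending. The
#' curve is anchored on the left by carrying the highest-threshold precision
#' horizontally down to recall 0 (so a perfect caller scores its maximum
#' recall); it is never extrapolated beyond the largest observed recall.
#'
#' @inheritParams confusion
#' @return object of class `pr_curve`: `points` data.frame (threshold,
#'   precision, recall) and `auc`.
#' @export
pr_curve <- function(preds, truth, tolerance = 0L, strict_strand = FALSE) {
  if (nrow(preds) == 0) {
    return(structure(list(points = data.frame(threshold = integer(0),
                                              precision = numeric(0),
                                              recall = numeric(0)),
                          auc = 0), class = "pr_curve"))
  }
  stopifnot(nrow(truth) > 0)
  hit <- match_predictions(preds, truth, tolerance, strict_strand)
  pts <- lapply(seq_len(max(preds$support)), function(t) {
    keep <- preds$support >= t
    n_det <- sum(keep)
    if (n_det == 0) return(NULL)
    tp <- sum(hit & keep)
    data.frame(threshold = t, precision = tp / n_det, recall = tp / nrow(truth))
  })
  pts <- do.call(rbind, pts)
  o <- order(pts$recall, -pts$threshold)
  r <- c(0, pts$recall[o])               # left anchor at recall 0,
  p <- c(pts$precision[o][1], pts$precision[o])  # constant precision
  auc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  structure(list(points = pts, auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("precision-recall curve: %d threshold(s), AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  o <- order(x$points$recall)
  plot(x$points$recall[o], x$points$precision[o], type = "b",
       xlab = "Recall", ylab = "Precision", ylim = c(0, 1), ...)
  invisible(x)
}

#' Truth-free false-positive summary
#'
#' On a dataset known to contain no circular junctions (a linear background),
#' the filtered candidate count and its total junction-read support indicate
#' a caller's false-positive burden.
#'
#' @inheritParams confusion
#' @return list with `n_detected` and `total_support`.
#' @export
background_summary <- function(preds, min_support = 2L) {
  det <- preds[preds$support >= min_support, , drop = FALSE]
  list(n_detected = nrow(det), total_support = sum(det$support))
}

#' Differences between two evaluations (b minus a)
#'
#' Differences are taken on the two-decimal-rounded percentages, so printed
#' drops such as -7.61 arise exactly from the rounded operands.
#'
#' @param counts_a,counts_b `confusion_counts` sharing the same truth size.
#' @return list with `delta_precision` and `delta_sensitivity` (percent
#'   points).
#' @export
delta_metrics <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "confusion_counts"),
            inherits(counts_b, "confusion_counts"))
  if (counts_a$n_truth != counts_b$n_truth) {
    stop("confusion counts have different truth sizes")
  }
  dp <- round(100 * counts_b$precision, 2) - round(100 * counts_a$precision, 2)
  ds <- round(100 * counts_b$sensitivity, 2) - round(100 * counts_a$sensitivity, 2)
  list(delta_precision = dp, delta_sensitivity = ds)
}
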