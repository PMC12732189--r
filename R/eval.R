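#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named list: accuracy, sensitivity, specificity, precision, f1 and
#'   the counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve by threshold sweep
#'
#' @param scores predicted probabilities (higher = more abnormal).
#' @param labels binary labels (1 = abnormal).
#' @return data frame of (threshold, fpr, tpr) from (1,1) down to (0,0)
#'   coverage, sorted by fpr.
#' @export
roc_points <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  out <- data.frame(threshold = thr, fpr = NA_real_, tpr = NA_real_)
  for (i in seq_along(thr)) {
    call_pos <- scores >= thr[i]
    out$tpr[i] <- if (pos > 0) sum(call_pos & labels == 1) / pos else NA_real_
    out$fpr[i] <- if (neg > 0) sum(call_pos & labels == 0) / neg else NA_real_
  }
  out
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' Equals the normalized Mann-Whitney pairwise-comparison statistic.
#'
#' @param scores,labels as in [roc_points()].
#' @return AUC in `[0, 1]`, or `NA` (with a warning) for a single-class set.
#' @export
auc_trapezoid <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    warning("AUC is undefined for a single-class label set")
    return(NA_real_)
  }
  r <- roc_points(scores, labels)
  ord <- order(r$fpr, r$tpr)
  x <- r$fpr[ord]; y <- r$tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Evaluate predicted scores against labels
#'
#' Confusion counts at the decision threshold, the five headline metrics,
#' the ROC sweep and the trapezoidal AUC.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels (1 = abnormal).
#' @param threshold decision threshold (default 0.5).
#' @return a `metrics_report` list.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1); fp <- sum(call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1); tn <- sum(!call_pos & labels == 0)
  m <- confusion_metrics(tp, fp, tn, fn)
  auc <- if (length(unique(labels)) < 2L) {
    warning("AUC is undefined for a single-class label set")
    NA_real_
  } else auc_trapezoid(scores, labels)
  structure(c(m, list(auc = auc, roc = roc_points(scores, labels),
                      threshold = threshold, n = length(scores))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  acc %.3f  sens %.3f  spec %.3f  prec %.3f  F1 %.3f  AUC %s\n",
              x$n, x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Paired t-test on per-fold metrics
#'
#' Two-sided paired t-test of `a - b` with `n - 1` degrees of freedom, with
#' explicit handling of the degenerate zero-variance cases that arise when
#' two methods score identically on every fold.
#'
#' @param a,b equal-length numeric vectors (one value per fold).
#' @return list with `t`, `p`, `df`, and `degenerate` (TRUE when the
#'   difference has zero variance).
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s < 1e-10 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, degenerate = FALSE)
}
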