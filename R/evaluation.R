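#' Threshold-averaged weighted one-vs-rest ROC and PR curves
#'
#' AUROC and AUPRC are defined for binary classifiers, so the 4-class
#' task is scored one-versus-rest: at each prediction threshold `t` in
#' `[0, 1]`, every class's true-positive rate, false-positive rate,
#' precision and recall are computed from the rule
#' `predicted positive iff p[, c] >= t`, then averaged across classes
#' with weights equal to the number of observations whose true target is
#' that class. Sweeping the thresholds traces the weighted ROC and PR
#' curves; areas are obtained by trapezoidal integration. The default
#' threshold grid is 1001 equally spaced points in `[0, 1]` plus every
#' observed score, which makes the areas insensitive to the grid.
#'
#' For a class with no predicted positives at a threshold, precision is
#' taken as 1 (the empty-prediction limit). With a single target class
#' present the metrics are undefined and returned as `NA` with
#' `undefined = TRUE`.
#'
#' @param p numeric matrix (n x 4) of class probabilities.
#' @param targets integer true class codes (0:3).
#' @param thresholds optional numeric vector of thresholds; the
#'   observed scores are always added.
#' @return list with `auroc`, `auprc`, `roc` (data.frame threshold /
#'   fpr / tpr), `pr` (threshold / recall / precision), `class_weights`,
#'   and `undefined`.
#' @export
weighted_ovr_curves <- function(p, targets, thresholds = NULL) {
  stopifnot(is.matrix(p), ncol(p) == 4, nrow(p) == length(targets))
  targets <- as.integer(targets)
  counts <- tabulate(targets + 1L, nbins = 4)
  if (sum(counts > 0) < 2) {
    return(list(auroc = NA_real_, auprc = NA_real_, roc = NULL, pr = NULL,
                class_weights = counts, undefined = TRUE))
  }
  if (is.null(thresholds)) thresholds <- seq(0, 1, length.out = 1001)
  th <- sort(unique(c(thresholds, as.vector(p))), decreasing = TRUE)
  n <- length(targets)
  tpr_w <- fpr_w <- prec_w <- rep(0, length(th))
  wsum <- sum(counts)
  for (c in 0:3) {
    if (counts[c + 1] == 0) next
    s <- p[, c + 1]
    pos <- sort(s[targets == c])
    neg <- sort(s[targets != c])
    np <- length(pos); nn <- length(neg)
    tp <- np - findInterval(th, pos, left.open = TRUE)
    fp <- nn - findInterval(th, neg, left.open = TRUE)
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
    wgt <- counts[c + 1] / wsum
    tpr_w <- tpr_w + wgt * tp / np
    fpr_w <- fpr_w + wgt * (if (nn > 0) fp / nn else 0)
    prec_w <- prec_w + wgt * prec
  }
  # thresholds descend, so fpr/tpr (and recall) ascend
  roc <- data.frame(threshold = th, fpr = fpr_w, tpr = tpr_w)
  pr <- data.frame(threshold = th, recall = tpr_w, precision = prec_w)
  auroc <- trapezoid(c(0, fpr_w, 1), c(0, tpr_w, 1))
  auprc <- trapezoid(c(0, tpr_w), c(prec_w[1], prec_w))
  list(auroc = auroc, auprc = auprc, roc = roc, pr = pr,
       class_weights = counts, undefined = FALSE)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Argmax accuracy
#'
#' Proportion of observations whose highest predicted probability falls
#' on the true target class; ties break to the lowest class code.
#'
#' @inheritParams weighted_ovr_curves
#' @return a proportion in [0, 1]; `NA` for an empty input.
#' @export
accuracy_argmax <- function(p, targets) {
  if (!length(targets)) return(NA_real_)
  mean(argmax_class(p) == as.integer(targets))
}

#' Worsening-reformulated sensitivity and specificity
#'
#' Sensitivity and specificity are adapted to the multiclass setting by
#' binarizing on MLS worsening: the true label is 1 when the future
#' target class exceeds the current class, and the predicted label is 1
#' when the argmax predicted class exceeds the current class. A
#' persistence predictor (always predicting the current class) thus has
#' sensitivity 0 and specificity 1. A side with no observations yields
#' `NA` for the corresponding metric.
#'
#' @inheritParams weighted_ovr_curves
#' @param current integer current class codes (0:3).
#' @return list with `sensitivity` and `specificity`.
#' @export
worsening_metrics <- function(p, targets, current) {
  stopifnot(length(targets) == length(current))
  truth <- as.integer(targets) > as.integer(current)
  pred <- argmax_class(p) > as.integer(current)
  sens <- if (any(truth)) mean(pred[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!pred[!truth]) else NA_real_
  list(sensitivity = sens, specificity = spec)
}

#' Evaluate predictions on the overall or filtered observation set
#'
#' Computes the five evaluation metrics - threshold-averaged weighted
#' one-vs-rest AUROC and AUPRC, argmax accuracy, and
#' worsening-reformulated sensitivity and specificity - on either every
#' valid observation (`mode = "overall"`) or only the transition
#' observations whose target class differs from the current class
#' (`mode = "filtered"`). Undefined metrics (empty subset, single-class
#' subset, one-sided worsening labels) are reported as `NA`, never
#' silently dropped.
#'
#' @param p numeric probability matrix aligned with `targets`.
#' @param targets,current,filtered per-observation target class, current
#'   class and transition flag.
#' @param mode `"overall"` or `"filtered"`.
#' @return one-row data.frame: mode, n, auroc, auprc, accuracy,
#'   sensitivity, specificity.
#' @export
evaluate_predictions <- function(p, targets, current, filtered,
                                 mode = c("overall", "filtered")) {
  mode <- match.arg(mode)
  keep <- !is.na(targets)
  if (mode == "filtered") keep <- keep & filtered %in% TRUE
  p <- p[keep, , drop = FALSE]
  targets <- targets[keep]
  current <- current[keep]
  if (!nrow(p)) {
    return(data.frame(mode = mode, n = 0L, auroc = NA_real_,
                      auprc = NA_real_, accuracy = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_))
  }
  cv <- weighted_ovr_curves(p, targets)
  wm <- worsening_metrics(p, targets, current)
  data.frame(mode = mode, n = nrow(p), auroc = cv$auroc, auprc = cv$auprc,
             accuracy = accuracy_argmax(p, targets),
             sensitivity = wm$sensitivity, specificity = wm$specificity)
}

#' Summarize per-split metrics with 95% confidence intervals
#'
#' Mean and t-based 95% confidence interval (`mean +/- t[0.975, n-1] *
#' sd / sqrt(n)`) of each metric across split-level values. Undefined
#' (NA) split values propagate with reduced n; a metric undefined in
#' every split stays NA.
#'
#' @param metrics data.frame of per-split metric rows, e.g. from
#'   [evaluate_predictions()] with a `split` column; all numeric
#'   columns except `split` and `n` are summarized, grouped by `mode`
#'   if present.
#' @return data.frame with columns mode, metric, mean, ci_lo, ci_hi,
#'   n_splits.
#' @export
summarize_splits <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1)
  mcols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                   c("split", "n"))
  modes <- if ("mode" %in% names(metrics)) unique(metrics$mode) else ""
  rows <- list()
  for (md in modes) {
    sub <- if (nzchar(md)) metrics[metrics$mode == md, , drop = FALSE] else metrics
    for (mc in mcols) {
      v <- sub[[mc]]
      v <- v[!is.na(v)]
      k <- length(v)
      if (k == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          mode = md, metric = mc, mean = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, n_splits = 0L)
        next
      }
      m <- mean(v)
      half <- if (k > 1) {
        stats::qt(0.975, df = k - 1) * stats::sd(v) / sqrt(k)
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        mode = md, metric = mc, mean = m,
        ci_lo = if (k > 1) m - half else NA_real_,
        ci_hi = if (k > 1) m + half else NA_real_, n_splits = k)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
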