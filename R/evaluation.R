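#' Confusion matrix for binary classification
#'
#' @param truth,pred Equal-length vectors of class labels drawn from the two
#'   known classes.
#' @param positive The positive class label (default `"E"`).
#' @return An object of class `confusion_matrix` with counts `tp`, `fn`,
#'   `fp`, `tn` and the declared positive class.
#' @export
confusion <- function(truth, pred, positive = "E") {
  if (length(truth) != length(pred)) {
    stop("confusion: truth and pred lengths differ", call. = FALSE)
  }
  if (length(truth) < 1) stop("confusion: empty input", call. = FALSE)
  classes <- sort(unique(as.character(truth)))
  if (!positive %in% classes) {
    stop("confusion: positive class not present in truth", call. = FALSE)
  }
  unknown <- setdiff(unique(c(as.character(truth), as.character(pred))), classes)
  if (length(unknown) > 0) {
    stop("confusion: unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  is_pos_t <- truth == positive
  is_pos_p <- pred == positive
  structure(
    list(
      tp = sum(is_pos_t & is_pos_p), fn = sum(is_pos_t & !is_pos_p),
      fp = sum(!is_pos_t & is_pos_p), tn = sum(!is_pos_t & !is_pos_p),
      positive = positive, classes = classes
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, specificity, sensitivity (recall) and F1 score, all
#' on the 0-100 percentage scale. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0 or 100.
#'
#' @param cm A [confusion()] result.
#' @return A one-row tibble: `accuracy`, `precision`, `specificity`,
#'   `sensitivity`, `f1`, `n`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n < 1) stop("cm_metrics: all-zero confusion matrix", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  precision <- rate(cm$tp, cm$tp + cm$fp)
  sensitivity <- rate(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(sensitivity) || precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  tibble::tibble(
    accuracy = rate(cm$tp + cm$tn, n),
    precision = precision,
    specificity = rate(cm$tn, cm$tn + cm$fp),
    sensitivity = sensitivity,
    f1 = f1,
    n = n
  )
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores (ties grouped), yielding a monotone
#' ROC polyline from (0, 0) to (1, 1); AUC by trapezoidal integration, which
#' equals the Mann-Whitney U statistic normalized by `n_pos * n_neg`.
#'
#' @param scores Real decision scores, larger = more positive.
#' @param truth Class labels.
#' @param positive Positive class label (default `"E"`).
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "E") {
  if (any(!is.finite(scores))) stop("roc_auc: non-finite scores", call. = FALSE)
  is_pos <- truth == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc: need at least one sample of each class", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_pos) / n_neg, numeric(1))
  roc <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Consolidated per-model, per-split metrics report
#'
#' One row per (model, split) with the display convention of the package's
#' summary tables: percentages rounded half-up to one decimal, AUC to four.
#'
#' @param results A list of entries, each a list with fields `model`, `split`,
#'   `truth`, `pred` and optionally `scores`.
#' @param positive Positive class label.
#' @return A tibble `model`, `split`, `accuracy`, `precision`, `specificity`,
#'   `sensitivity`, `f1`, `auc`.
#' @export
fit_report <- function(results, positive = "E") {
  round_half_up <- function(x, d) {
    ifelse(is.na(x), NA_real_, floor(x * 10^d + 0.5) / 10^d)
  }
  purrr::map_dfr(results, function(r) {
    stopifnot(!is.null(r$model), !is.null(r$split))
    m <- cm_metrics(confusion(r$truth, r$pred, positive))
    auc <- if (!is.null(r$scores)) roc_auc(r$scores, r$truth, positive)$auc else NA_real_
    tibble::tibble(
      model = r$model, split = r$split,
      accuracy = round_half_up(m$accuracy, 1),
      precision = round_half_up(m$precision, 1),
      specificity = round_half_up(m$specificity, 1),
      sensitivity = round_half_up(m$sensitivity, 1),
      f1 = round_half_up(m$f1, 1),
      auc = round_half_up(auc, 4)
    )
  })
}

#' Reconstruct confusion matrices from printed percentage metrics
#'
#' Exhaustively enumerates all non-negative integer matrices
#' `(tp, fn, fp, tn)` with `tp + fn + fp + tn == n_total` and returns those
#' whose metrics match the supplied percentages within `tol` (after rounding
#' to the given precision). Useful to recover the underlying counts from a
#' published metrics table row.
#'
#' @param n_total Total number of samples.
#' @param accuracy,precision,specificity,sensitivity,f1 Printed percentage
#'   metrics; `NA` to leave unconstrained.
#' @param n_positive Optional known number of true-positive-class samples
#'   (`tp + fn`); needed to pin down rows whose metrics alone do not
#'   determine the class split (e.g. an all-100 row).
#' @param tol Matching tolerance on each metric (default 0.05, i.e. agreement
#'   to one printed decimal).
#' @return A tibble of matching matrices with their exact metrics.
#' @export
reconstruct_confusion <- function(n_total, accuracy = NA, precision = NA,
                                  specificity = NA, sensitivity = NA, f1 = NA,
                                  n_positive = NA, tol = 0.05) {
  # vectorized enumeration of all weak compositions of n_total into 4 parts
  grid <- expand.grid(tp = 0:n_total, fn = 0:n_total, fp = 0:n_total)
  grid <- grid[grid$tp + grid$fn + grid$fp <= n_total, ]
  tp <- grid$tp
  fn <- grid$fn
  fp <- grid$fp
  tn <- n_total - tp - fn - fp
  rate <- function(num, den) {
    out <- 100 * num / den
    out[den == 0] <- NA_real_
    out
  }
  acc <- 100 * (tp + tn) / n_total
  prec <- rate(tp, tp + fp)
  spec <- rate(tn, tn + fp)
  sens <- rate(tp, tp + fn)
  f1v <- ifelse(is.na(prec) | is.na(sens) | prec + sens == 0, NA_real_,
                2 * prec * sens / (prec + sens))
  keep <- rep(TRUE, length(tp))
  if (!is.na(n_positive)) keep <- keep & (tp + fn == n_positive)
  match_metric <- function(keep, vals, target) {
    if (is.na(target)) return(keep)
    # small absolute slack so a tolerance like 0.05 is not defeated by the
    # binary representation of the printed decimals
    keep & !is.na(vals) & abs(vals - target) <= tol + 1e-9
  }
  keep <- match_metric(keep, acc, accuracy)
  keep <- match_metric(keep, prec, precision)
  keep <- match_metric(keep, spec, specificity)
  keep <- match_metric(keep, sens, sensitivity)
  keep <- match_metric(keep, f1v, f1)
  tibble::tibble(
    tp = as.integer(tp[keep]), fn = as.integer(fn[keep]),
    fp = as.integer(fp[keep]), tn = as.integer(tn[keep]),
    accuracy = acc[keep], precision = prec[keep], specificity = spec[keep],
    sensitivity = sens[keep], f1 = f1v[keep],
    n = rep(n_total, sum(keep))
  )
}
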