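#' Multi-class confusion matrix
#'
#' Entry (i, j) counts records with true class code i predicted as j
#' (codes 0..n_classes-1).
#'
#' @param y_true Integer vector of true class codes.
#' @param y_pred Integer vector of predicted class codes, same length.
#' @param n_classes Number of classes (default 3).
#' @return Integer `n_classes x n_classes` matrix of class
#'   `confusion_matrix`, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 3) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  codes <- c(y_true, y_pred)
  if (length(codes) > 0 &&
      (anyNA(codes) || any(codes < 0) || any(codes >= n_classes))) {
    stop("class codes must be integers in 0:", n_classes - 1, call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  if (length(y_true) > 0) {
    tab <- tabulate(y_true * n_classes + y_pred + 1L,
                    nbins = n_classes * n_classes)
    cm <- matrix(tab, n_classes, n_classes, byrow = TRUE)
  }
  nm <- if (n_classes == 3) class_labels() else as.character(0:(n_classes - 1))
  dimnames(cm) <- list(true = nm, predicted = nm)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

# One-vs-rest reduction: per-class TP/FN/FP/TN counts.
ovr_counts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  data.frame(class = rownames(cm), tp = tp, fn = fn, fp = fp, tn = tn,
             support = rowSums(cm), row.names = NULL,
             stringsAsFactors = FALSE)
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Confusion-matrix metric suite
#'
#' Computes the standard metric set from per-class one-vs-rest counts:
#' accuracy, precision, recall, F1, false-negative rate, false-positive
#' rate, misclassification rate (`1 - accuracy`, exactly), and optionally
#' the mean cross-entropy loss. Headline precision/recall use
#' support-weighted averaging — the convention under which weighted recall
#' is algebraically identical to accuracy — and the headline F1 is the
#' harmonic mean of that precision/recall pair. Headline FNR/FPR use macro
#' averaging by default (`rate_average = "micro"` pools the counts
#' instead). Zero-denominator cells resolve to 0 and set the
#' `zero_division` flag rather than producing NaN.
#'
#' @param cm A [confusion_matrix()].
#' @param losses Optional numeric vector of per-record cross-entropies;
#'   their mean is reported as `loss`.
#' @param rate_average `"macro"` (default) or `"micro"` averaging for the
#'   headline FNR and FPR.
#' @return An object of class `classification_metrics`: a list with
#'   headline `accuracy`, `precision`, `recall`, `f1`, `fnr`, `fpr`,
#'   `mc_rate`, `loss`, a `per_class` tibble, and a `zero_division` flag.
#' @export
classification_metrics <- function(cm, losses = NULL,
                                   rate_average = c("macro", "micro")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rate_average <- match.arg(rate_average)
  n <- sum(cm)
  oc <- ovr_counts(cm)
  precision_c <- safe_div(oc$tp, oc$tp + oc$fp)
  recall_c <- safe_div(oc$tp, oc$tp + oc$fn)
  f1_c <- safe_div(2 * precision_c * recall_c, precision_c + recall_c)
  fnr_c <- safe_div(oc$fn, oc$tp + oc$fn)
  fpr_c <- safe_div(oc$fp, oc$fp + oc$tn)
  zero_division <- any((oc$tp + oc$fp) == 0) || any((oc$tp + oc$fn) == 0)

  w <- if (n > 0) oc$support / n else rep(0, nrow(oc))
  precision <- sum(w * precision_c)
  recall <- sum(w * recall_c)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- if (n > 0) sum(diag(cm)) / n else NA_real_
  if (rate_average == "macro") {
    fnr <- mean(fnr_c)
    fpr <- mean(fpr_c)
  } else {
    fnr <- safe_div(sum(oc$fn), sum(oc$tp + oc$fn))
    fpr <- safe_div(sum(oc$fp), sum(oc$fp + oc$tn))
  }
  structure(
    list(
      accuracy = accuracy,
      mc_rate = 1 - accuracy,
      precision = precision,
      recall = recall,
      f1 = f1,
      fnr = fnr,
      fpr = fpr,
      loss = if (is.null(losses)) NA_real_ else mean(losses),
      per_class = tibble::tibble(
        class = oc$class, support = oc$support,
        tp = oc$tp, fn = oc$fn, fp = oc$fp, tn = oc$tn,
        precision = precision_c, recall = recall_c, f1 = f1_c,
        fnr = fnr_c, fpr = fpr_c
      ),
      rate_average = rate_average,
      zero_division = zero_division
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f | fnr %.4f | fpr %.4f | mc_rate %.4f",
    x$accuracy, x$precision, x$recall, x$f1, x$fnr, x$fpr, x$mc_rate))
  if (!is.na(x$loss)) cat(sprintf(" | loss %.4f", x$loss))
  cat("\n")
  invisible(x)
}

#' One-vs-rest ROC AUC by pairwise concordance
#'
#' For each class c, the AUC of score column c for the binary task
#' "class c vs rest", computed with the rank (Mann-Whitney) formula in
#' which tied positive/negative score pairs count one half. A class absent
#' from `y_true` (or covering all of it) has undefined AUC and is reported
#' as `NA`; the macro average is taken over the defined classes.
#'
#' @param y_true Integer vector of true class codes.
#' @param probas Numeric `n x n_classes` matrix of class scores; rows are
#'   expected to sum to 1.
#' @return List with `per_class` (named numeric vector, `NA` when
#'   undefined) and `macro` (mean over defined classes).
#' @export
roc_auc_ovr <- function(y_true, probas) {
  probas <- as.matrix(probas)
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == nrow(probas))
  k <- ncol(probas)
  auc <- rep(NA_real_, k)
  for (c in seq_len(k) - 1L) {
    pos <- y_true == c
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) next
    r <- rank(probas[, c + 1L])  # average ranks handle ties as 1/2
    auc[c + 1L] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  names(auc) <- if (k == 3) class_labels() else as.character(0:(k - 1))
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}
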