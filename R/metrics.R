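# Evaluation metrics: 5-class confusion matrix, accuracy, one-vs-rest
# precision/recall/F1, macro F1 and Cohen's kappa with the multiclass
# marginal-product chance agreement.

label_index <- function(y) {
  stages <- sleep_stages()
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    idx <- match(y, stages)
    if (anyNA(idx)) stop("invalid stage label(s): ",
                         paste(unique(y[is.na(idx)]), collapse = ", "))
    return(idx)
  }
  y <- as.integer(y)
  if (any(y < 0L | y > 4L)) stop("integer labels must be in 0..4")
  y + 1L
}

#' 5-class confusion matrix
#'
#' Entry (i, j) counts epochs of true stage i predicted as stage j. Labels
#' may be stage names (W, N1, N2, N3, R), factors, or integers 0..4.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return 5x5 integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  ti <- label_index(y_true); pi <- label_index(y_pred)
  stages <- sleep_stages()
  cm <- matrix(0L, 5L, 5L, dimnames = list(true = stages, pred = stages))
  for (k in seq_along(ti)) cm[ti[k], pi[k]] <- cm[ti[k], pi[k]] + 1L
  cm
}

#' One-vs-rest counts and rates for one class
#'
#' TP/TN/FP/FN of class `c` against the rest, with precision
#' P = TP / (TP + FP) and recall R = TP / (TP + FN); 0/0 is defined as 0.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param c class index 1..5 or stage name.
#' @export
binary_rates <- function(cm, c) {
  if (is.character(c)) c <- match(c, sleep_stages())
  tp <- cm[c, c]
  fp <- sum(cm[-c, c])
  fn <- sum(cm[c, -c])
  tn <- sum(cm) - tp - fp - fn
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       precision = safe_div(tp, tp + fp), recall = safe_div(tp, tp + fn))
}

#' Overall accuracy
#'
#' Proportion of correctly classified epochs: trace / total.
#' @param cm confusion matrix.
#' @export
accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm)) / n
}

#' Per-class and macro F1
#'
#' F1_c = 2 P R / (P + R) per class (0 when P + R = 0), and the unweighted
#' mean over the five stages.
#'
#' @param cm confusion matrix.
#' @return list with `per_class` (named vector) and `macro_f1`.
#' @export
f1_scores <- function(cm) {
  f1 <- vapply(1:5, function(c) {
    br <- binary_rates(cm, c)
    if (br$precision + br$recall == 0) 0
    else 2 * br$precision * br$recall / (br$precision + br$recall)
  }, 0)
  names(f1) <- sleep_stages()
  list(per_class = f1, macro_f1 = mean(f1))
}

#' Cohen's kappa
#'
#' kappa = (accuracy - Pe) / (1 - Pe) with the multiclass chance agreement
#' Pe = sum_c row_c * col_c / n^2 (the marginal-product form). When Pe = 1
#' (all mass in one cell), kappa is undefined and reported as 0 with a
#' warning.
#'
#' @param cm confusion matrix.
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) {
    warning("chance agreement Pe = 1; kappa undefined, reporting 0")
    return(0)
  }
  (accuracy(cm) - pe) / (1 - pe)
}

#' Full evaluation report
#'
#' Confusion matrix plus accuracy, per-class precision/recall/F1, macro F1,
#' Cohen's kappa and the chance agreement Pe.
#'
#' @param y_true,y_pred label vectors (names, factors or integers 0..4).
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  n <- sum(cm)
  per <- lapply(1:5, function(c) binary_rates(cm, c))
  f1 <- f1_scores(cm)
  structure(list(
    confusion = cm, n = n, accuracy = accuracy(cm),
    precision = stats::setNames(vapply(per, `[[`, 0, "precision"),
                                sleep_stages()),
    recall = stats::setNames(vapply(per, `[[`, 0, "recall"),
                             sleep_stages()),
    f1 = f1$per_class, macro_f1 = f1$macro_f1,
    Pe = sum(rowSums(cm) * colSums(cm)) / n^2,
    kappa = suppressWarnings(cohens_kappa(cm))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  accuracy = %.4f  macro F1 = %.4f  kappa = %.4f\n",
              x$n, x$accuracy, x$macro_f1, x$kappa))
  print(x$confusion)
  invisible(x)
}
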