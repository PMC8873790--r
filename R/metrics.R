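# Multiclass evaluation: confusion matrix, overall accuracy ("GAA" — the
# global average accuracy, i.e. the fraction of correctly classified test
# segments), Cohen's kappa, macro precision/recall/F1, and micro-averaged
# one-vs-rest ROC/AUC.

#' Confusion matrix, overall accuracy and per-class accuracy
#'
#' @param y_true,y_pred equal-length integer label vectors (0..3).
#' @param n_classes number of classes.
#' @return list with `confusion` (rows = true, columns = predicted),
#'   `gaa` (trace/n) and `per_class_accuracy` (row-normalized diagonal;
#'   NA for classes absent from `y_true`).
#' @export
confusion_and_gaa <- function(y_true, y_pred, n_classes = 4L) {
  if (length(y_true) == 0L) stop("empty label vectors")
  stopifnot(length(y_true) == length(y_pred))
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, lv), factor(y_pred, lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = lv, pred = lv))
  rs <- rowSums(cm)
  list(confusion = cm,
       gaa = sum(diag(cm)) / sum(cm),
       per_class_accuracy = ifelse(rs > 0, diag(cm) / rs, NA_real_))
}

#' Cohen's kappa from a confusion matrix
#'
#' kappa = (p_o - p_e) / (1 - p_e) with observed agreement p_o = trace/n
#' and chance agreement p_e = sum_c row_c * col_c / n^2. A degenerate
#' table with p_e = 1 (all mass in one cell) returns 0 with a warning.
#'
#' @param confusion square count matrix (rows = true, columns = predicted).
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(confusion) {
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warning("degenerate confusion matrix (chance agreement 1); kappa set to 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Macro-averaged precision, recall and F1
#'
#' Per class: P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); the macro
#' score is the unweighted mean. An empty denominator makes that class's
#' metric 0 (with a warning), a documented convention.
#'
#' @param confusion square count matrix (rows = true, columns = predicted).
#' @return list with `precision`, `recall`, `f1` (macro) and the
#'   `per_class` data.frame.
#' @export
macro_prf1 <- function(confusion) {
  if (sum(confusion) == 0) stop("empty confusion matrix")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  warn <- FALSE
  div0 <- function(a, b) {
    out <- ifelse(b > 0, a / b, 0)
    if (any(b == 0)) warn <<- TRUE
    out
  }
  prec <- div0(tp, tp + fp)
  rec <- div0(tp, tp + fn)
  f1 <- div0(2 * prec * rec, prec + rec)
  if (warn) warning("empty denominator for at least one class; metric set to 0")
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(precision = prec, recall = rec, f1 = f1))
}

#' Micro-averaged one-vs-rest ROC curve and AUC
#'
#' Flattens the (sample, class) indicator/score pairs into one binary
#' problem, sweeps thresholds over the distinct scores (ties grouped), and
#' integrates by the trapezoidal rule.
#'
#' @param y_true integer labels 0..(k-1).
#' @param probs n x k matrix of class scores (rows need not be calibrated
#'   but typically sum to 1).
#' @return list with `roc_points` (data.frame fpr/tpr from (0,0) to
#'   (1,1)) and `auc`.
#' @export
multiclass_roc_auc <- function(y_true, probs) {
  if (length(unique(y_true)) < 2L) {
    stop("ROC requires at least two classes present in y_true")
  }
  k <- ncol(probs)
  truth <- as.vector(vapply(seq_len(k) - 1L,
                            function(c) as.numeric(y_true == c),
                            numeric(length(y_true))))
  score <- as.vector(probs)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  n_pos <- sum(truth); n_neg <- length(truth) - n_pos
  # cumulative counts at each distinct-score threshold (ties grouped)
  tp <- cumsum(truth); fp <- cumsum(1 - truth)
  last_of_group <- c(diff(score) != 0, TRUE)
  tpr <- c(0, tp[last_of_group] / n_pos)
  fpr <- c(0, fp[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full evaluation report for one test set
#'
#' @param y_true,y_pred integer labels 0..3.
#' @param probs optional n x 4 probability matrix (enables ROC/AUC).
#' @return object of class `eval_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred, probs = NULL) {
  cg <- confusion_and_gaa(y_true, y_pred)
  pr <- macro_prf1(cg$confusion)
  roc <- if (!is.null(probs)) multiclass_roc_auc(y_true, probs) else NULL
  structure(list(confusion = cg$confusion, gaa = cg$gaa,
                 per_class_accuracy = cg$per_class_accuracy,
                 kappa = cohens_kappa(cg$confusion),
                 precision = pr$precision, recall = pr$recall, f1 = pr$f1,
                 roc_points = roc$roc_points, auc = roc$auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: GAA %.4f | kappa %.4f | P %.4f R %.4f F1 %.4f%s\n",
              x$gaa, x$kappa, x$precision, x$recall, x$f1,
              if (!is.null(x$auc)) sprintf(" | AUC %.4f", x$auc) else ""))
  cat("confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
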