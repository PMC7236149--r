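#' Subset accuracy (exact-match rate)
#'
#' Mean of the exact-match indicators `[Z_i = Y_i]` over the test set
#' (Iverson bracket formulation).
#'
#' @param pred,truth Label vectors of equal positive length.
#' @return Accuracy in `[0, 1]`.
#' @export
subset_accuracy <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop("pred and truth must be nonempty and of equal length")
  }
  mean(as.character(pred) == as.character(truth))
}

#' Confusion matrix, weighted F1 and multiclass Matthews correlation
#'
#' Computes the confusion matrix (rows = true labels), the
#' support-weighted mean F1 score over classes, and the multiclass
#' Matthews correlation coefficient in the Gorodkin confusion-matrix
#' generalization. A class with no predicted (or no true) instances
#' contributes an F1 of 0; when the truth contains a single label the
#' MCC is undefined and reported as 0 with a warning.
#'
#' @param pred,truth Label vectors of equal length.
#' @param labels Label universe and ordering; defaults to the sorted
#'   union of observed labels.
#' @return List with `confusion`, `f1_weighted`, `mcc`, `per_class`
#'   (precision/recall/F1/support per class) and `accuracy`.
#' @export
classification_scores <- function(pred, truth,
                                  labels = sort(unique(c(as.character(pred),
                                                         as.character(truth))))) {
  pred <- factor(as.character(pred), levels = labels)
  truth <- factor(as.character(truth), levels = labels)
  if (length(pred) != length(truth)) stop("length mismatch")
  cm <- table(truth = truth, pred = pred)
  k <- length(labels)
  tp <- diag(cm)
  support <- rowSums(cm)
  predn <- colSums(cm)
  precision <- ifelse(predn > 0, tp / predn, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  f1w <- sum(f1 * support) / sum(support)

  if (sum(support > 0) < 2L) {
    warning("MCC undefined for single-label truth; reporting 0")
    mcc <- 0
  } else {
    n <- sum(cm)
    c_sum <- sum(tp)
    num <- c_sum * n - sum(support * predn)
    den <- sqrt(n^2 - sum(predn^2)) * sqrt(n^2 - sum(support^2))
    mcc <- if (den == 0) 0 else num / den
  }
  list(confusion = cm,
       f1_weighted = f1w,
       mcc = mcc,
       per_class = data.frame(label = labels, precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.numeric(support)),
       accuracy = sum(tp) / sum(cm))
}

#' One-vs-rest ROC AUC per class with micro average
#'
#' Per-class AUC uses the rank (Mann-Whitney) formulation with midrank
#' tie handling; the micro average pools every (sample, class) binary
#' decision using the corresponding probability column. Classes absent
#' from the truth get `NA`.
#'
#' @param prob `n x k` probability (or score) matrix with column names
#'   matching the label universe.
#' @param truth Label vector of length `n`.
#' @return List with `per_class` (named AUC vector) and `micro`.
#' @export
roc_auc_ovr <- function(prob, truth) {
  prob <- as.matrix(prob)
  truth <- as.character(truth)
  if (is.null(colnames(prob))) stop("prob must have label column names")
  if (nrow(prob) != length(truth)) stop("length mismatch")
  auc1 <- function(score, pos) {
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(score, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  per <- vapply(colnames(prob), function(l) auc1(prob[, l], truth == l),
                numeric(1))
  pooled_pos <- as.vector(vapply(colnames(prob), function(l) truth == l,
                                 logical(length(truth))))
  micro <- auc1(as.vector(prob), pooled_pos)
  list(per_class = per, micro = micro)
}

#' Evaluate predictions into a single report
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param prob Optional probability matrix for ROC AUC.
#' @param labels Label universe.
#' @return An `evaluation_report`: list with `n`, `accuracy`,
#'   `f1_weighted`, `mcc`, `confusion`, `per_class`, and (when `prob`
#'   is given) `auc` and `auc_micro`.
#' @export
evaluation_report <- function(pred, truth, prob = NULL,
                              labels = topology_labels()) {
  sc <- classification_scores(pred, truth, labels = labels)
  rep <- list(n = length(truth), accuracy = sc$accuracy,
              f1_weighted = sc$f1_weighted, mcc = sc$mcc,
              confusion = sc$confusion, per_class = sc$per_class)
  if (!is.null(prob)) {
    auc <- roc_auc_ovr(prob, truth)
    rep$auc <- auc$per_class
    rep$auc_micro <- auc$micro
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d acc=%.3f F1w=%.3f MCC=%.3f\n",
              x$n, x$accuracy, x$f1_weighted, x$mcc))
  invisible(x)
}

#' Aggregate evaluation reports over independent trials
#'
#' Per-metric mean and sample standard deviation over trials, plus the
#' per-cell mean confusion matrix and mean per-class recall. Order of
#' the reports does not matter.
#'
#' @param reports List of [evaluation_report()] objects with identical
#'   label sets (at least 2).
#' @return List with `n_trials`, a `metrics` data frame
#'   (metric/mean/sd), `mean_confusion` and `mean_recall`.
#' @export
aggregate_trials <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  lab_sets <- lapply(reports, function(r) rownames(r$confusion))
  if (!all(vapply(lab_sets, identical, logical(1), lab_sets[[1]]))) {
    stop("reports have heterogeneous label sets")
  }
  metric <- function(name) vapply(reports, `[[`, numeric(1), name)
  metrics <- data.frame(
    metric = c("accuracy", "f1_weighted", "mcc"),
    mean = c(mean(metric("accuracy")), mean(metric("f1_weighted")),
             mean(metric("mcc"))),
    sd = c(stats::sd(metric("accuracy")), stats::sd(metric("f1_weighted")),
           stats::sd(metric("mcc")))
  )
  cms <- lapply(reports, function(r) unclass(r$confusion))
  mean_cm <- Reduce(`+`, cms) / length(cms)
  recalls <- vapply(reports, function(r) {
    stats::setNames(r$per_class$recall, r$per_class$label)
  }, numeric(nrow(reports[[1]]$per_class)))
  list(n_trials = length(reports), metrics = metrics,
       mean_confusion = mean_cm,
       mean_recall = rowMeans(recalls))
}
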