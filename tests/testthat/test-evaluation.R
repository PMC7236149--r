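test_that("subset accuracy is the exact-match mean", {
  expect_equal(subset_accuracy(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(subset_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(subset_accuracy(c("a", "b", "c", "a"), c("a", "b", "c", "b")),
               0.75)
  expect_error(subset_accuracy(character(0), character(0)), "nonempty")
})

test_that("classification scores match a from-scratch contingency oracle", {
  # hand-built 3x3 confusion: rows true (a, b, c), columns predicted
  cm <- matrix(c(5, 1, 0,
                 2, 6, 1,
                 0, 2, 3), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  truth <- rep(rownames(cm), times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(i) rep(colnames(cm), times = cm[i, ])))
  sc <- classification_scores(pred, truth)
  expect_equal(unclass(sc$confusion), unclass(as.table(cm)),
               ignore_attr = TRUE)

  # from-scratch per-class F1 and support weighting
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(sc$f1_weighted, sum(f1 * rowSums(cm)) / sum(cm))

  # Gorodkin multiclass MCC from the confusion matrix
  n <- sum(cm)
  num <- sum(diag(cm)) * n - sum(rowSums(cm) * colSums(cm))
  den <- sqrt(n^2 - sum(colSums(cm)^2)) * sqrt(n^2 - sum(rowSums(cm)^2))
  expect_equal(sc$mcc, num / den)
  expect_equal(sc$accuracy, sum(diag(cm)) / n)
})

test_that("perfect and degenerate predictions hit the metric extremes", {
  truth <- rep(c("x", "y", "z"), times = c(4, 3, 3))
  perfect <- classification_scores(truth, truth)
  expect_equal(perfect$f1_weighted, 1)
  expect_equal(perfect$mcc, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_warning(
    single <- classification_scores(rep("x", 3), rep("x", 3)),
    "MCC undefined"
  )
  expect_equal(single$mcc, 0)
})

test_that("independent predictions give near-zero MCC", {
  set.seed(77)
  truth <- sample(c("a", "b", "c"), 10000, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 10000, replace = TRUE)
  expect_lt(abs(classification_scores(pred, truth)$mcc), 0.05)
})

test_that("one-vs-rest AUC matches extremes, the null, and midranks", {
  prob <- rbind(c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1),
                c(0.1, 0.8, 0.1), c(0.2, 0.1, 0.7))
  colnames(prob) <- c("a", "b", "c")
  truth <- c("a", "a", "b", "c")
  res <- roc_auc_ovr(prob, truth)
  expect_equal(unname(res$per_class), c(1, 1, 1))
  inv <- roc_auc_ovr(1 - prob, truth)
  expect_equal(unname(inv$per_class), c(0, 0, 0))

  # scores independent of labels: AUC ~ 0.5
  set.seed(5)
  n <- 5000
  p <- matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  t_rand <- sample(c("a", "b", "c"), n, replace = TRUE)
  null_auc <- roc_auc_ovr(p, t_rand)
  expect_true(all(abs(null_auc$per_class - 0.5) < 0.03))
  expect_lt(abs(null_auc$micro - 0.5), 0.03)

  # midrank ties: equal scores share credit
  tie <- matrix(c(0.5, 0.5, 0.5, 0.5), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  res_tie <- roc_auc_ovr(tie, c("a", "b"))
  expect_equal(unname(res_tie$per_class), c(0.5, 0.5))

  # class absent from the truth reports NA
  absent <- roc_auc_ovr(prob, c("a", "a", "b", "b"))
  expect_true(is.na(absent$per_class[["c"]]))
})

test_that("micro AUC is invariant under a consistent label permutation", {
  set.seed(8)
  prob <- matrix(runif(60), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  truth <- sample(c("a", "b", "c"), 20, replace = TRUE)
  base <- roc_auc_ovr(prob, truth)$micro
  perm <- c(b = "a", c = "b", a = "c")   # relabeling map
  prob2 <- prob[, c("b", "c", "a")]
  colnames(prob2) <- perm
  truth2 <- unname(perm[truth])
  expect_equal(roc_auc_ovr(prob2, truth2)$micro, base)
})

test_that("trial aggregation reports mean, sd and mean confusion", {
  mk <- function(acc) {
    pred <- c(rep("heterogeneous", round(acc * 10)),
              rep("rugged", 10 - round(acc * 10)))
    evaluation_report(pred, rep("heterogeneous", 10),
                      labels = topology_labels())
  }
  r1 <- suppressWarnings(mk(0.7))
  r2 <- suppressWarnings(mk(0.8))
  agg <- aggregate_trials(list(r1, r2))
  acc_row <- agg$metrics[agg$metrics$metric == "accuracy", ]
  expect_equal(acc_row$mean, 0.75)
  expect_equal(acc_row$sd, sd(c(0.7, 0.8)))
  # permutation invariance
  agg_rev <- aggregate_trials(list(r2, r1))
  expect_equal(agg_rev$metrics, agg$metrics)
  expect_equal(agg_rev$mean_confusion, agg$mean_confusion)
  # identical reports: zero sd
  agg_same <- aggregate_trials(list(r1, r1))
  expect_true(all(agg_same$metrics$sd == 0))
  expect_error(aggregate_trials(list(r1)), "at least 2")
})

test_that("accuracy equals the confusion-matrix trace over n", {
  set.seed(13)
  truth <- sample(topology_labels(), 60, replace = TRUE)
  pred <- sample(topology_labels(), 60, replace = TRUE)
  sc <- classification_scores(pred, truth, labels = topology_labels())
  expect_equal(subset_accuracy(pred, truth),
               sum(diag(sc$confusion)) / 60)
  # diagonal confusion implies weighted F1 == accuracy
  sc_diag <- classification_scores(truth, truth, labels = topology_labels())
  expect_equal(sc_diag$f1_weighted, sc_diag$accuracy)
})
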