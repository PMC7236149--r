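# small separable feature sets keep the trainer tests fast

sep_features <- function(n_per = 10, p = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0), ncol = p),
    matrix(rnorm(n_per * p, 4), ncol = p),
    matrix(rnorm(n_per * p, 8), ncol = p)
  )
  list(x = x, y = rep(topology_labels(), each = n_per))
}

test_that("class splits are disjoint, exhaustive and seeded", {
  names <- sprintf("cls%02d", 1:38)
  s1 <- split_classes(names, seed = 4)
  expect_length(s1$train, 19L)
  expect_length(s1$test, 19L)
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_setequal(c(s1$train, s1$test), names)
  expect_identical(split_classes(names, seed = 4), s1)
  expect_false(identical(split_classes(names, seed = 5)$train, s1$train))
  expect_error(split_classes(names[1:37], seed = 1), "evenly")
  s2 <- split_classes(names[1:36], seed = 1, train_fraction = 2 / 3)
  expect_length(s2$train, 24L)
})

test_that("svm one-vs-one training selects by cross-validated accuracy", {
  d <- sep_features(n_per = 8, seed = 2)
  fit <- train_svm(d$x, d$y, costs = c(0.1, 1), kernels = "linear",
                   folds = 4, seed = 3)
  # 3 labels -> 3 binary one-against-one machines
  expect_length(kernlab::alpha(fit$model), 3L)
  pred <- predict(fit, d$x)
  expect_equal(subset_accuracy(pred$label, d$y), 1.0)
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
  # chosen point maximizes the CV accuracy table the trainer reports
  expect_equal(fit$cv$accuracy[fit$cv$cost == fit$chosen$cost &
                                 fit$cv$kernel == fit$chosen$kernel],
               max(fit$cv$accuracy))
  # independent re-evaluation of the CV grid reproduces the selection
  refit <- train_svm(d$x, d$y, costs = c(0.1, 1), kernels = "linear",
                     folds = 4, seed = 3)
  expect_equal(refit$chosen, fit$chosen)
  expect_equal(refit$cv$accuracy, fit$cv$accuracy)
  expect_error(train_svm(d$x, rep("smooth", nrow(d$x))), "at least 2")
})

test_that("separable two-class features reach training accuracy 1", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, -3), ncol = 6), matrix(rnorm(60, 3), ncol = 6))
  y <- rep(c("smooth", "rugged"), each = 10)
  fit <- train_svm(x, y, costs = 1, kernels = "linear", folds = 4, seed = 1)
  expect_equal(subset_accuracy(predict(fit, x)$label, y), 1.0)
})

test_that("random forest explores the full 2x2x2 grid and is seeded", {
  d <- sep_features(n_per = 6, p = 10, seed = 5)
  fit <- train_rf(d$x, d$y, folds = 3, seed = 9)
  expect_equal(nrow(fit$cv), 8L)
  expect_setequal(unique(fit$cv$n_trees), c(50, 100))
  expect_setequal(unique(fit$cv$min_split), c(2, 5))
  expect_setequal(unique(fit$cv$min_leaf), c(1, 3))
  p1 <- predict(fit, d$x)
  fit2 <- train_rf(d$x, d$y, folds = 3, seed = 9)
  p2 <- predict(fit2, d$x)
  expect_identical(p1$prob, p2$prob)
  expect_gte(subset_accuracy(p1$label, d$y), 0.95)
  # probabilities are per-class tree vote fractions
  votes <- predict(fit$model, d$x, type = "vote")
  expect_equal(unclass(p1$prob), unclass(votes), ignore_attr = TRUE)
})

test_that("predictions are proper distributions with argmax labels", {
  d <- sep_features(n_per = 5, p = 8, seed = 11)
  for (fit in list(train_svm(d$x, d$y, costs = 1, kernels = "linear",
                             folds = 3, seed = 2),
                   train_rf(d$x, d$y, n_trees = 50, min_split = 2,
                            min_leaf = 1, folds = 3, seed = 2))) {
    pred <- predict(fit, d$x)
    expect_true(all(pred$prob >= 0))
    expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
    idx <- max.col(pred$prob, ties.method = "first")
    expect_identical(pred$label, colnames(pred$prob)[idx])
  }
})

test_that("the CNN builds the reference three-block architecture", {
  cfg <- cnn_config_full()
  net <- altopo:::cnn_init(c(220L, 360L, 3L), cfg, seed = 1)
  expect_equal(dim(net$params$Wc1), c(32L, 9L * 3L))
  expect_equal(dim(net$params$Wc2), c(64L, 9L * 32L))
  expect_equal(dim(net$params$Wc3), c(128L, 9L * 64L))
  expect_equal(dim(net$params$Wo), c(3L, cfg$dense[2]))
  # geometry: three 2x2 poolings halve each spatial dimension
  expect_equal(net$geo$final[1:2], c(220L %/% 8L, 360L %/% 8L))
})

test_that("a scaled-down CNN learns trivially separable intensity classes", {
  set.seed(21)
  n_per <- 12
  imgs <- list()
  labels <- character(0)
  shades <- c(heterogeneous = 0.2, rugged = 0.5, smooth = 0.85)
  for (lab in names(shades)) {
    for (i in seq_len(n_per)) {
      m <- matrix(shades[[lab]] + rnorm(256, 0, 0.04), 16, 16)
      imgs[[length(imgs) + 1L]] <- al_image(pmin(pmax(m, 0), 1))
      labels <- c(labels, lab)
    }
  }
  cfg <- cnn_config(filters = c(4L, 8L, 8L), dense = c(16L, 8L),
                    dropout = 0, lr = 0.003, max_epochs = 30,
                    patience = 8, input_size = c(16L, 16L),
                    batch_size = 12L)
  hold <- c(1:3, 13:15, 25:27)
  fit <- train_cnn(imgs[-hold], labels[-hold], config = cfg, seed = 5)
  pred <- predict(fit, imgs[hold])
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
  expect_gte(subset_accuracy(pred$label, labels[hold]), 0.95)
})

test_that("diverging learning rates are skipped during the CNN search", {
  set.seed(3)
  imgs <- lapply(1:12, function(i) {
    al_image(matrix(ifelse(i <= 6, 0.2, 0.8) + rnorm(64, 0, 0.03), 8, 8))
  })
  labels <- rep(c("smooth", "rugged"), each = 6)
  cfg <- cnn_config(filters = c(2L, 2L, 2L), dense = c(4L, 4L),
                    dropout = 0, max_epochs = 8, input_size = c(8L, 8L))
  grid <- list(relu_alpha = 0.1, dropout = 0, dense1 = 4L, dense2 = 4L,
               lr = c(1e30, 0.01))
  fit <- train_cnn(imgs, labels, config = cfg, grid = grid, budget = Inf,
                   seed = 2)
  status <- vapply(fit$search_log, `[[`, character(1), "status")
  expect_true("diverged" %in% status)
  expect_equal(fit$config$lr, 0.01)
})
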