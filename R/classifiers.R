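#' Topology label set
#'
#' The three landscape topology labels in their documented (and
#' tie-breaking) order.
#'
#' @return Character vector `c("heterogeneous", "rugged", "smooth")`.
#' @export
topology_labels <- function() c("heterogeneous", "rugged", "smooth")

#' Split activity classes into disjoint training and test halves
#'
#' Classes (not images) are split, so that no image of a test class can
#' occur in training: leakage is impossible by construction.
#'
#' @param names Character vector of class names (even count for the
#'   default 50/50 split).
#' @param seed Integer seed.
#' @param train_fraction Training fraction (default 0.5).
#' @return A `class_split`: list with `train`, `test`, `seed`.
#' @export
split_classes <- function(names, seed = 1L, train_fraction = 0.5) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("class names must be unique")
  n_train <- length(names) * train_fraction
  if (abs(n_train - round(n_train)) > 1e-9) {
    stop("train fraction ", train_fraction, " does not split ",
         length(names), " classes evenly; pass a suitable train_fraction")
  }
  set.seed(seed)
  train <- sort(sample(names, round(n_train)))
  structure(list(train = train, test = sort(setdiff(names, train)),
                 seed = seed),
            class = "class_split")
}

# validated factor of topology labels in canonical order
as_topology_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), topology_labels())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = topology_labels())
}

# seeded stratified fold assignment
make_folds <- function(y, folds, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

# group-disjoint fold assignment: all images of one group (activity
# class) share a fold, so cross-validation measures generalization to
# unseen classes rather than to further views of seen landscapes
make_group_folds <- function(groups, folds, seed) {
  groups <- as.character(groups)
  set.seed(seed)
  gs <- sample(unique(groups))
  folds <- min(folds, length(gs))
  fold_of <- stats::setNames(rep_len(seq_len(folds), length(gs)), gs)
  list(id = unname(fold_of[groups]), folds = folds)
}

#' Train the CNN topology classifier
#'
#' Splits the training images 80/20 into internal training and
#' validation parts (stratified, seeded), evaluates candidate
#' hyperparameter settings drawn from `grid` (validation subset
#' accuracy; diverging settings are scored as failed and skipped),
#' then refits the best setting on all training images for the number
#' of epochs that was optimal under validation. A setting whose
#' validation accuracy stays at chance level has not converged and is
#' retried from up to two further derived initializations (judged on
#' the validation part only) before entering the comparison.
#'
#' @param images List of single- or 3-channel `al_image`s, or an
#'   `H x W x C x N` array.
#' @param labels Topology labels, one per image.
#' @param config Base [cnn_config()]; grid candidates override its
#'   `relu_alpha`, `dropout`, `dense` and `lr` fields.
#' @param grid Hyperparameter grid as in [cnn_default_grid()], or
#'   `NULL` to train `config` as-is.
#' @param budget Number of grid settings to evaluate (sampled without
#'   replacement from the full Cartesian grid, seeded); `Inf` explores
#'   the full grid.
#' @param groups Optional grouping vector (e.g. activity class names,
#'   one per image). When given, the internal 80/20 validation part is
#'   held out at the group level, so that no landscape contributes
#'   views to both sides; this mirrors the class-disjoint outer
#'   evaluation and keeps early stopping honest about generalization.
#' @param seed Integer seed.
#' @param verbose Log per-epoch losses.
#' @return An `al_classifier` of kind `"cnn"`.
#' @export
train_cnn <- function(images, labels, config = cnn_config(), grid = NULL,
                      budget = 4L, groups = NULL, seed = 1L,
                      verbose = FALSE) {
  y <- as_topology_factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 labels present")
  x <- images_to_tensor(images, config$input_size)
  n <- dim(x)[4]
  if (length(y) != n) stop("labels and images differ in length")

  candidates <- if (is.null(grid)) {
    list(config)
  } else {
    full <- expand.grid(a = grid$relu_alpha, dr = grid$dropout,
                        d1 = grid$dense1, d2 = grid$dense2, lr = grid$lr)
    set.seed(seed)
    take <- if (is.finite(budget) && budget < nrow(full)) {
      sample.int(nrow(full), budget)
    } else {
      seq_len(nrow(full))
    }
    lapply(take, function(i) {
      cfg <- config
      cfg$relu_alpha <- full$a[i]
      cfg$dropout <- full$dr[i]
      cfg$dense <- c(full$d1[i], full$d2[i])
      cfg$lr <- full$lr[i]
      cfg
    })
  }

  if (is.null(groups)) {
    fold <- make_folds(y, 5L, seed)  # fold 1 (~20%) is the validation part
    val <- fold == 1L
  } else {
    stopifnot(length(groups) == n)
    set.seed(seed)
    gs <- sample(unique(as.character(groups)))
    n_val <- max(1L, round(length(gs) / 5))
    val <- as.character(groups) %in% gs[seq_len(n_val)]
  }
  yi <- as.integer(y)
  best <- NULL
  log <- list()
  chance <- 1 / nlevels(droplevels(y))
  for (ci in seq_along(candidates)) {
    cfg <- candidates[[ci]]
    # a fit whose validation accuracy stays at chance has not converged;
    # retry from a different (derived) initialization, judged on the
    # validation part only
    cand_best <- NULL
    for (attempt in 0:2) {
      fit <- cnn_train_core(x[, , , !val, drop = FALSE], yi[!val], cfg,
                            seed = seed + 7919L * attempt,
                            x_val = x[, , , val, drop = FALSE],
                            y_val = yi[val], verbose = verbose)
      if (fit$diverged || fit$best_epoch == 0L) next
      pr <- cnn_predict_prob(fit$net, x[, , , val, drop = FALSE])
      acc <- mean(max.col(pr, ties.method = "first") == yi[val])
      if (is.null(cand_best) || acc > cand_best$acc) {
        cand_best <- list(acc = acc, epochs = fit$best_epoch,
                          seed = seed + 7919L * attempt)
      }
      if (acc >= chance + 0.1) break
    }
    if (is.null(cand_best)) {
      log[[ci]] <- list(config = cfg, status = "diverged")
      next
    }
    log[[ci]] <- list(config = cfg, status = "ok",
                      val_accuracy = cand_best$acc,
                      best_epoch = cand_best$epochs,
                      init_seed = cand_best$seed)
    if (is.null(best) || cand_best$acc > best$acc) {
      best <- list(cfg = cfg, acc = cand_best$acc,
                   epochs = cand_best$epochs, seed = cand_best$seed)
    }
  }
  if (is.null(best)) stop("all CNN hyperparameter settings diverged")
  refit <- cnn_train_core(x, yi, best$cfg, seed = best$seed,
                          fixed_epochs = max(best$epochs, 1L),
                          verbose = verbose)
  if (refit$diverged) {
    stop("CNN refit diverged with the selected hyperparameters")
  }
  structure(
    list(kind = "cnn", net = refit$net, config = best$cfg,
         labels = topology_labels(), input_size = config$input_size,
         channels = dim(x)[3], search_log = log,
         val_accuracy = best$acc, seed = seed),
    class = "al_classifier"
  )
}

# convert image list / array to an (H, W, C, N) tensor, resizing if asked
images_to_tensor <- function(images, input_size = NULL) {
  if (is.array(images) && length(dim(images)) == 4L) {
    x <- images
  } else {
    if (inherits(images, "al_image")) images <- list(images)
    mats <- lapply(images, function(im) {
      px <- if (inherits(im, "al_image")) im$pixels else im
      if (is.matrix(px)) array(px, c(dim(px), 1L)) else px
    })
    d <- dim(mats[[1]])
    if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
      stop("all images must share dimensions and channel count")
    }
    x <- array(unlist(mats, use.names = FALSE), c(d, length(mats)))
  }
  if (!is.null(input_size) &&
      !identical(dim(x)[1:2], as.integer(input_size))) {
    d <- dim(x)
    out <- array(0, c(input_size[1], input_size[2], d[3], d[4]))
    for (i in seq_len(d[4])) {
      r <- EBImage::resize(x[, , , i, drop = TRUE], w = input_size[1],
                           h = input_size[2], filter = "bilinear")
      out[, , , i] <- array(as.numeric(r),
                            c(input_size[1], input_size[2], d[3]))
    }
    x <- out
  }
  x
}

#' Train the SVM topology classifier
#'
#' Grid search over cost and kernel by seeded stratified
#' cross-validation (default tenfold) on the flattened image feature
#' vectors, followed by a refit of the winning setting on all training
#' data. Features are standardized with training statistics
#' (constant features get unit scale). Multi-class handling is
#' one-against-one (3 binary machines for 3 labels).
#'
#' For image-scale feature vectors (79,200 features) per-pair kernel
#' evaluation inside the solver is the bottleneck, so all kernels are
#' precomputed once from a single BLAS Gram product and passed to the
#' solver as kernel matrices: linear `<x, y> / p`, polynomial
#' `(<x, y> / p + 1)^3`, and radial `exp(-||x - y||^2 / (p * vbar))`
#' with `vbar` the mean feature variance after standardization (the
#' common `1 / (n_features * variance)` bandwidth heuristic). The
#' `1 / p` normalization only rescales the kernel (equivalently the
#' cost unit) and keeps the solver well conditioned.
#'
#' @param features Numeric `n x p` feature matrix (see
#'   [normalize_and_flatten()]).
#' @param labels Topology labels.
#' @param costs Cost grid (default `c(0.01, 0.1, 1)`).
#' @param kernels Kernel grid (default linear, polynomial, radial).
#' @param folds Cross-validation folds (default 10; capped at the
#'   number of groups when `groups` is given).
#' @param budget Number of grid points to evaluate (seeded subsample);
#'   `Inf` explores the full grid.
#' @param groups Optional grouping vector (activity class per image).
#'   When given, CV folds are group-disjoint, so model selection
#'   measures generalization to unseen classes instead of to further
#'   views of landscapes already in the fold — mirroring the
#'   class-disjoint outer evaluation.
#' @param seed Integer seed.
#' @return An `al_classifier` of kind `"svm"` with fields `cv` (the CV
#'   accuracy table) and `chosen`.
#' @export
train_svm <- function(features, labels, costs = c(0.01, 0.1, 1),
                      kernels = c("linear", "polynomial", "radial"),
                      folds = 10L, budget = Inf, groups = NULL,
                      seed = 1L) {
  kernels <- match.arg(kernels, c("linear", "polynomial", "radial"),
                       several.ok = TRUE)
  y <- droplevels(as_topology_factor(labels))
  if (nlevels(y) < 2L) stop("need at least 2 labels present")
  x <- as.matrix(features)
  p <- ncol(x)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(x^2) - ctr^2)
  scl[!is.finite(scl) | scl < 1e-9] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  g_lin <- tcrossprod(xs) / p
  vbar <- max(mean(colMeans(xs^2) - colMeans(xs)^2), 1e-12)

  kernel_matrix <- function(kernel, g, sq_row, sq_col) {
    switch(kernel,
           linear = g,
           polynomial = (g + 1)^3,
           radial = {
             d2 <- outer(sq_row, sq_col, "+") - 2 * g
             d2[d2 < 0] <- 0
             exp(-d2 / vbar)
           })
  }
  sq <- diag(g_lin)

  grid <- expand.grid(cost = costs, kernel = kernels,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  if (is.finite(budget) && budget < nrow(grid)) {
    grid <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
  }
  if (is.null(groups)) {
    folds <- min(folds, min(table(y)))
    fold <- make_folds(y, folds, seed)
  } else {
    stopifnot(length(groups) == nrow(x))
    gf <- make_group_folds(groups, folds, seed)
    fold <- gf$id
    folds <- gf$folds
  }
  grid$accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    kmat <- kernel_matrix(grid$kernel[gi], g_lin, sq, sq)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      set.seed(seed + f)
      fit <- kernlab::ksvm(kernlab::as.kernelMatrix(kmat[tr, tr]),
                           y[tr], C = grid$cost[gi])
      ktest <- kernlab::as.kernelMatrix(
        kmat[te, tr[kernlab::SVindex(fit)], drop = FALSE]
      )
      correct <- correct + sum(kernlab::predict(fit, ktest) == y[te])
    }
    grid$accuracy[gi] <- correct / length(y)
  }
  bi <- which.max(grid$accuracy)
  kmat <- kernel_matrix(grid$kernel[bi], g_lin, sq, sq)
  set.seed(seed)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(kmat), y,
                       C = grid$cost[bi], prob.model = TRUE)
  structure(
    list(kind = "svm", model = fit, center = ctr, scale = scl,
         train_scaled = xs, sq_train = sq, vbar = vbar,
         kernel = grid$kernel[bi],
         labels = levels(y), cv = grid,
         chosen = grid[bi, c("cost", "kernel")], seed = seed),
    class = "al_classifier"
  )
}

# kernel rows between new scaled data and the training set
svm_new_kernel <- function(object, xs_new) {
  p <- ncol(xs_new)
  g <- tcrossprod(xs_new, object$train_scaled) / p
  switch(object$kernel,
         linear = g,
         polynomial = (g + 1)^3,
         radial = {
           sq_new <- rowSums(xs_new^2) / p
           d2 <- outer(sq_new, object$sq_train, "+") - 2 * g
           d2[d2 < 0] <- 0
           exp(-d2 / object$vbar)
         })
}

#' Train the random forest topology classifier
#'
#' Grid search over ensemble size, minimum samples for a split and
#' minimum leaf size by seeded stratified cross-validation (default
#' tenfold), then a refit on all training data. The minimum-leaf and
#' minimum-split controls are mapped onto the forest's terminal node
#' size as `nodesize = max(min_leaf, floor(min_split / 2))`, the
#' closest available control of the underlying implementation.
#'
#' @param features Numeric `n x p` matrix.
#' @param labels Topology labels.
#' @param n_trees Ensemble size grid (default `c(50, 100)`).
#' @param min_split Minimum node size eligible for splitting (default
#'   `c(2, 5)`).
#' @param min_leaf Minimum terminal node size (default `c(1, 3)`).
#' @param folds Cross-validation folds (default 10; capped at the
#'   number of groups when `groups` is given).
#' @param budget Grid points to evaluate; `Inf` = full grid (8 points).
#' @param groups Optional grouping vector; group-disjoint CV folds as
#'   in [train_svm()].
#' @param seed Integer seed.
#' @return An `al_classifier` of kind `"rf"` with the CV table in `cv`.
#' @export
train_rf <- function(features, labels, n_trees = c(50L, 100L),
                     min_split = c(2L, 5L), min_leaf = c(1L, 3L),
                     folds = 10L, budget = Inf, groups = NULL,
                     seed = 1L) {
  y <- droplevels(as_topology_factor(labels))
  if (nlevels(y) < 2L) stop("need at least 2 labels present")
  x <- as.matrix(features)
  grid <- expand.grid(n_trees = n_trees, min_split = min_split,
                      min_leaf = min_leaf)
  set.seed(seed)
  if (is.finite(budget) && budget < nrow(grid)) {
    grid <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
  }
  if (is.null(groups)) {
    folds <- min(folds, min(table(y)))
    fold <- make_folds(y, folds, seed)
  } else {
    stopifnot(length(groups) == nrow(x))
    gf <- make_group_folds(groups, folds, seed)
    fold <- gf$id
    folds <- gf$folds
  }
  grid$accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    nodesize <- max(grid$min_leaf[gi], grid$min_split[gi] %/% 2L)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      set.seed(seed + f)
      fit <- randomForest::randomForest(
        x[tr, , drop = FALSE], y[tr], ntree = grid$n_trees[gi],
        nodesize = nodesize
      )
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    grid$accuracy[gi] <- correct / length(y)
  }
  bi <- which.max(grid$accuracy)
  set.seed(seed)
  fit <- randomForest::randomForest(
    x, y, ntree = grid$n_trees[bi],
    nodesize = max(grid$min_leaf[bi], grid$min_split[bi] %/% 2L)
  )
  structure(
    list(kind = "rf", model = fit, labels = levels(y), cv = grid,
         chosen = grid[bi, c("n_trees", "min_split", "min_leaf")],
         seed = seed),
    class = "al_classifier"
  )
}

#' @export
print.al_classifier <- function(x, ...) {
  cat(sprintf("<al_classifier> %s over labels {%s}\n", x$kind,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Predict topology labels and probabilities
#'
#' @param object An `al_classifier`.
#' @param newdata For `cnn`: image list or tensor; for `svm`/`rf`: a
#'   feature matrix with the training feature count.
#' @param ... Unused.
#' @return List with `prob` (`n x k` matrix, columns in the
#'   classifier's label order) and `label` (argmax labels; ties break
#'   toward the earlier label in that order).
#' @export
predict.al_classifier <- function(object, newdata, ...) {
  prob <- switch(object$kind,
    cnn = {
      x <- images_to_tensor(newdata, object$input_size)
      if (dim(x)[3] != object$channels) {
        stop("channel count does not match the training encoding")
      }
      p <- cnn_predict_prob(object$net, x)
      colnames(p) <- object$labels
      p
    },
    svm = {
      x <- as.matrix(newdata)
      if (ncol(x) != length(object$center)) {
        stop("feature count does not match training (", ncol(x), " vs ",
             length(object$center), ")")
      }
      xs <- scale(x, center = object$center, scale = object$scale)
      kn <- svm_new_kernel(object, xs)
      ktest <- kernlab::as.kernelMatrix(
        kn[, kernlab::SVindex(object$model), drop = FALSE]
      )
      pr <- kernlab::predict(object$model, ktest, type = "probabilities")
      pr[, object$labels, drop = FALSE]
    },
    rf = {
      x <- as.matrix(newdata)
      pr <- stats::predict(object$model, x, type = "prob")
      pr[, object$labels, drop = FALSE]
    },
    stop("unknown classifier kind: ", object$kind)
  )
  idx <- max.col(prob, ties.method = "first")
  list(prob = prob, label = object$labels[idx])
}
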