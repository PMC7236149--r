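#' Convolutional network configuration
#'
#' Architecture and training settings for the landscape-image CNN:
#' three convolutional blocks (3 x 3 filters, leaky-ReLU activation,
#' 2 x 2 max-pooling, dropout), a flattening step, two dense layers
#' with dropout, and a 3-way softmax output. The reference architecture
#' uses 32/64/128 filters on full-resolution images; for desk-scale
#' training the default scales the images down and uses fewer filters,
#' keeping the architecture shape.
#'
#' @param filters Filter counts of the three convolutional blocks.
#' @param kernel Convolution kernel side (3).
#' @param pool Max-pooling window side (2).
#' @param relu_alpha Leaky-ReLU negative slope (0 gives plain ReLU).
#' @param dropout Dropout rate applied after each pooling and dense
#'   layer.
#' @param dense Sizes of the two intermediate dense layers.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience on validation loss.
#' @param input_size `c(H, W)` to which input images are resized before
#'   entering the network (`NULL` keeps the native size).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(filters = c(8L, 16L, 32L), kernel = 3L, pool = 2L,
                       relu_alpha = 0.1, dropout = 0.1,
                       dense = c(32L, 16L), lr = 0.001,
                       batch_size = 32L, max_epochs = 50L, patience = 5L,
                       input_size = c(28L, 44L)) {
  stopifnot(length(filters) == 3L, kernel == 3L, pool == 2L,
            relu_alpha >= 0, relu_alpha <= 0.5,
            dropout >= 0, dropout < 1, length(dense) == 2L, lr > 0)
  structure(list(filters = as.integer(filters), kernel = 3L, pool = 2L,
                 relu_alpha = relu_alpha, dropout = dropout,
                 dense = as.integer(dense), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 input_size = if (is.null(input_size)) NULL else
                   as.integer(input_size)),
            class = "cnn_config")
}

#' Reference (full-scale) CNN configuration
#'
#' The full architecture: 32/64/128 filters and full-resolution
#' 220 x 360 input.
#'
#' @param ... Overrides passed to [cnn_config()].
#' @return A `cnn_config`.
#' @export
cnn_config_full <- function(...) {
  args <- utils::modifyList(
    list(filters = c(32L, 64L, 128L), dense = c(64L, 32L),
         input_size = NULL),
    list(...)
  )
  do.call(cnn_config, args)
}

#' Default CNN hyperparameter grid
#'
#' The search grid for internal validation: leaky-ReLU slope sampled
#' from \[0, 0.5\], dropout from \{0, 0.1, 0.3\}, dense sizes from
#' \{16, 32, 64, 128\}, and the Adam learning-rate grid
#' \{100, 10, 1, 0.1, 0.01, 0.005, 0.001, 5e-5, 5e-6\}. Extreme
#' learning rates routinely diverge; diverging grid points are scored
#' as failed and skipped during the search.
#'
#' @return Named list of candidate values per hyperparameter.
#' @export
cnn_default_grid <- function() {
  list(relu_alpha = c(0, 0.1, 0.3, 0.5),
       dropout = c(0, 0.1, 0.3),
       dense1 = c(16L, 32L, 64L, 128L),
       dense2 = c(16L, 32L, 64L, 128L),
       lr = c(100, 10, 1, 0.1, 0.01, 0.005, 0.001, 5e-5, 5e-6))
}

# ---- network internals -----------------------------------------------------

# layer geometry and im2col index tables for a given input size
cnn_geometry <- function(input_dim, config) {
  h <- input_dim[1]; w <- input_dim[2]; cch <- input_dim[3]
  layers <- list()
  for (l in 1:3) {
    hp <- h + 2L; wp <- w + 2L
    # rows ordered (di, dj, channel); columns ordered (i, then j)
    grid_i <- rep(seq_len(h), times = w)
    grid_j <- rep(seq_len(w), each = h)
    idx <- matrix(0L, 9L * cch, h * w)
    r <- 0L
    for (ch in seq_len(cch)) {
      for (dj in 0:2) {
        for (di in 0:2) {
          r <- r + 1L
          idx[r, ] <- (grid_i + di) + (grid_j + dj - 1L) * hp +
            (ch - 1L) * hp * wp
        }
      }
    }
    ho <- h %/% 2L; wo <- w %/% 2L
    layers[[l]] <- list(h = h, w = w, c = cch, idx = idx,
                        h_out = ho, w_out = wo,
                        k = config$filters[l])
    h <- ho; w <- wo; cch <- config$filters[l]
  }
  list(layers = layers, flat = h * w * cch, final = c(h, w, cch))
}

cnn_init <- function(input_dim, config, seed = 1L) {
  set.seed(seed)
  geo <- cnn_geometry(input_dim, config)
  he <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  }
  params <- list()
  for (l in 1:3) {
    lay <- geo$layers[[l]]
    params[[paste0("Wc", l)]] <- he(lay$k, 9L * lay$c)
    params[[paste0("bc", l)]] <- numeric(lay$k)
  }
  params$Wd1 <- he(config$dense[1], geo$flat)
  params$bd1 <- numeric(config$dense[1])
  params$Wd2 <- he(config$dense[2], config$dense[1])
  params$bd2 <- numeric(config$dense[2])
  params$Wo <- he(3L, config$dense[2])
  params$bo <- numeric(3L)
  list(params = params, geo = geo, config = config,
       input_dim = input_dim)
}

lrelu <- function(x, a) ifelse(x > 0, x, a * x)
lrelu_grad <- function(x, a) ifelse(x > 0, 1, a)

# pad an (H, W, C) array with one zero ring on the spatial dims
pad1 <- function(a) {
  d <- dim(a)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- a
  out
}

# forward pass for one sample; returns logits and caches when train
cnn_forward1 <- function(net, x, train = FALSE, drop_masks = NULL) {
  cfg <- net$config
  p <- net$params
  a <- if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  if (!is.null(net$input_center)) a <- a - net$input_center
  cache <- list()
  for (l in 1:3) {
    lay <- net$geo$layers[[l]]
    ap <- pad1(a)
    cols <- matrix(ap[lay$idx], nrow = nrow(lay$idx))
    z <- p[[paste0("Wc", l)]] %*% cols + p[[paste0("bc", l)]]
    act <- lrelu(z, cfg$relu_alpha)
    # act: k x (h*w) -> array (h, w, k)
    amap <- array(t(act), c(lay$h, lay$w, lay$k))
    pool <- maxpool2(amap)
    out <- pool$out
    if (train && cfg$dropout > 0) {
      m <- drop_masks[[paste0("conv", l)]]
      out <- out * m
    }
    if (train) {
      cache[[l]] <- list(cols = cols, z = z, amap_dim = dim(amap),
                         pool = pool)
    }
    a <- out
  }
  flat <- as.vector(a)
  z1 <- as.vector(p$Wd1 %*% flat + p$bd1)
  a1 <- lrelu(z1, cfg$relu_alpha)
  if (train && cfg$dropout > 0) a1 <- a1 * drop_masks$dense1
  z2 <- as.vector(p$Wd2 %*% a1 + p$bd2)
  a2 <- lrelu(z2, cfg$relu_alpha)
  if (train && cfg$dropout > 0) a2 <- a2 * drop_masks$dense2
  logits <- as.vector(p$Wo %*% a2 + p$bo)
  list(logits = logits, cache = cache, flat = flat, z1 = z1, a1 = a1,
       z2 = z2, a2 = a2, conv_out_dim = dim(a))
}

# 2x2 max pooling with argmax bookkeeping
maxpool2 <- function(a) {
  d <- dim(a)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  i1 <- seq_len(ho) * 2L - 1L
  j1 <- seq_len(wo) * 2L - 1L
  s <- cbind(as.vector(a[i1, j1, , drop = FALSE]),
             as.vector(a[i1 + 1L, j1, , drop = FALSE]),
             as.vector(a[i1, j1 + 1L, , drop = FALSE]),
             as.vector(a[i1 + 1L, j1 + 1L, , drop = FALSE]))
  which <- max.col(s, ties.method = "first")
  out <- array(s[cbind(seq_len(nrow(s)), which)], c(ho, wo, d[3]))
  list(out = out, which = which, in_dim = d)
}

maxpool2_backward <- function(dout, pool) {
  d <- pool$in_dim
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  da <- array(0, d)
  base_i <- rep(seq_len(ho) * 2L - 1L, times = wo * d[3])
  base_j <- rep(rep(seq_len(wo) * 2L - 1L, each = ho), times = d[3])
  base_k <- rep(seq_len(d[3]), each = ho * wo)
  off_i <- c(0L, 1L, 0L, 1L)[pool$which]
  off_j <- c(0L, 0L, 1L, 1L)[pool$which]
  da[cbind(base_i + off_i, base_j + off_j, base_k)] <- as.vector(dout)
  da
}

# backward pass for one sample; returns parameter gradients
cnn_backward1 <- function(net, fw, dlogits, drop_masks = NULL) {
  cfg <- net$config
  p <- net$params
  g <- list()
  g$Wo <- outer(dlogits, fw$a2)
  g$bo <- dlogits
  da2 <- as.vector(crossprod(p$Wo, dlogits))
  if (cfg$dropout > 0) da2 <- da2 * drop_masks$dense2
  dz2 <- da2 * lrelu_grad(fw$z2, cfg$relu_alpha)
  g$Wd2 <- outer(dz2, fw$a1)
  g$bd2 <- dz2
  da1 <- as.vector(crossprod(p$Wd2, dz2))
  if (cfg$dropout > 0) da1 <- da1 * drop_masks$dense1
  dz1 <- da1 * lrelu_grad(fw$z1, cfg$relu_alpha)
  g$Wd1 <- outer(dz1, fw$flat)
  g$bd1 <- dz1
  dflat <- as.vector(crossprod(p$Wd1, dz1))
  da <- array(dflat, fw$conv_out_dim)
  for (l in 3:1) {
    lay <- net$geo$layers[[l]]
    cache <- fw$cache[[l]]
    if (cfg$dropout > 0) da <- da * drop_masks[[paste0("conv", l)]]
    dpool <- maxpool2_backward(da, cache$pool)
    dact <- t(matrix(as.vector(dpool), ncol = lay$k))  # k x (h*w)
    dz <- dact * lrelu_grad(cache$z, cfg$relu_alpha)
    g[[paste0("Wc", l)]] <- tcrossprod(dz, cache$cols)
    g[[paste0("bc", l)]] <- rowSums(dz)
    if (l > 1L) {
      dcols <- crossprod(p[[paste0("Wc", l)]], dz)
      hp <- lay$h + 2L; wp <- lay$w + 2L
      dpad <- numeric(hp * wp * lay$c)
      sums <- rowsum(as.vector(dcols), group = as.vector(lay$idx))
      dpad[as.integer(rownames(sums))] <- sums
      dpad <- array(dpad, c(hp, wp, lay$c))
      da <- dpad[2:(lay$h + 1L), 2:(lay$w + 1L), , drop = FALSE]
    }
  }
  g
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# train a CNN on (H, W, C, N) data; returns fitted net and history
cnn_train_core <- function(x, y, config, seed = 1L, x_val = NULL,
                           y_val = NULL, fixed_epochs = NULL,
                           verbose = FALSE) {
  dims <- dim(x)
  n <- dims[4]
  nlev <- max(y)
  net <- cnn_init(dims[1:3], config, seed = seed)
  net$input_center <- mean(x)  # mostly-white frames: center for conditioning
  adam <- lapply(net$params, function(w) list(m = w * 0, v = w * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  set.seed(seed + 1L)
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  wait <- 0L
  history <- data.frame()
  max_ep <- if (is.null(fixed_epochs)) config$max_epochs else fixed_epochs
  for (epoch in seq_len(max_ep)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        masks <- if (config$dropout > 0) {
          make_drop_masks(net, config)
        } else {
          NULL
        }
        fw <- cnn_forward1(net, x[, , , i, drop = TRUE], train = TRUE,
                           drop_masks = masks)
        pr <- softmax(fw$logits)
        bl <- bl - log(max(pr[y[i]], 1e-12))
        dlog <- pr
        dlog[y[i]] <- dlog[y[i]] - 1
        g <- cnn_backward1(net, fw, dlog, drop_masks = masks)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      nb <- length(batch)
      ep_loss <- ep_loss + bl
      t_step <- t_step + 1
      for (nm in names(net$params)) {
        gr <- grads[[nm]] / nb
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * gr
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * gr^2
        mhat <- adam[[nm]]$m / (1 - b1^t_step)
        vhat <- adam[[nm]]$v / (1 - b2^t_step)
        net$params[[nm]] <- net$params[[nm]] -
          config$lr * mhat / (sqrt(vhat) + eps)
      }
      if (!all(vapply(net$params, function(w) all(is.finite(w)),
                      logical(1)))) {
        return(list(net = NULL, diverged = TRUE, history = history))
      }
    }
    ep_loss <- ep_loss / n
    val_loss <- NA_real_
    if (!is.null(x_val)) {
      val_loss <- cnn_loss(net, x_val, y_val)
      if (!is.finite(val_loss)) {
        return(list(net = NULL, diverged = TRUE, history = history))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = net$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %s", epoch, ep_loss,
                      format(val_loss, digits = 4)))
    }
    if (!is.null(x_val) && is.null(fixed_epochs) &&
        wait >= config$patience) {
      break
    }
  }
  if (!is.null(x_val) && best$epoch > 0L) net$params <- best$params
  list(net = net, diverged = FALSE, history = history,
       best_epoch = if (!is.null(x_val)) best$epoch else max_ep,
       nlev = nlev)
}

make_drop_masks <- function(net, config) {
  keep <- 1 - config$dropout
  masks <- list()
  for (l in 1:3) {
    lay <- net$geo$layers[[l]]
    masks[[paste0("conv", l)]] <-
      array(stats::rbinom(lay$h_out * lay$w_out * lay$k, 1L, keep) / keep,
            c(lay$h_out, lay$w_out, lay$k))
  }
  masks$dense1 <- stats::rbinom(config$dense[1], 1L, keep) / keep
  masks$dense2 <- stats::rbinom(config$dense[2], 1L, keep) / keep
  masks
}

cnn_loss <- function(net, x, y) {
  # unclamped cross-entropy: a softmax collapsed to exactly zero on the
  # true class (numerical blow-up) must surface as a non-finite loss so
  # the hyperparameter search can score the setting as diverged
  n <- dim(x)[4]
  loss <- 0
  for (i in seq_len(n)) {
    pr <- softmax(cnn_forward1(net, x[, , , i, drop = TRUE])$logits)
    loss <- loss - log(pr[y[i]])
  }
  loss / n
}

cnn_predict_prob <- function(net, x) {
  n <- dim(x)[4]
  t(vapply(seq_len(n), function(i) {
    softmax(cnn_forward1(net, x[, , , i, drop = TRUE])$logits)
  }, numeric(3)))
}
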