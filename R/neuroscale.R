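#' Fit a Neuroscale RBF-network embedding model
#'
#' Neuroscale is a parametric counterpart to multidimensional scaling:
#' compounds are mapped to the plane by a radial basis function (RBF)
#' network whose output coordinates are trained to preserve pairwise
#' Tanimoto distances (the same normalized Kruskal stress as
#' [stress()]). Being a trained map, it can project compounds that were
#' not part of training.
#'
#' RBF centers are chosen by k-medoids (partitioning around medoids) on
#' the Tanimoto distance matrix; the bandwidth is the median
#' center-to-center distance; activations are Gaussian in the Tanimoto
#' distance to each center. The linear output weights are initialized by
#' least squares onto an MDS embedding and refined by gradient (BFGS)
#' minimization of the stress of the composed map. When more than one
#' candidate center count is supplied, the count minimizing the mean
#' held-out stress under `folds`-fold cross-validation (default
#' sevenfold) is selected and the model is refit on all data.
#'
#' @param fps Integer 0/1 fingerprint matrix (one compound per row).
#' @param d Optional precomputed Tanimoto distance matrix; computed from
#'   `fps` when `NULL`.
#' @param candidate_counts Candidate numbers of RBF centers; default
#'   `c(5, 10, 20, 40)` capped at `n/2`.
#' @param seed Integer seed (fold assignment, MDS initialization).
#' @param folds Cross-validation folds (default 7). `n` must be at
#'   least `2 * folds`; for smaller sets pass fewer folds.
#' @param max_iter BFGS iteration cap for weight refinement.
#' @return A `neuroscale_model`: list with `centers` (fingerprint rows),
#'   `width`, `weights` (`(k+1) x 2`, first row the bias), `n_rbf`,
#'   `stress` (training stress), `cv` (per-candidate mean CV stress, if
#'   run) and `fp_length`.
#' @seealso [neuroscale_transform()], [neuroscale_project()]
#' @export
neuroscale_fit <- function(fps, d = NULL, candidate_counts = NULL,
                           seed = 1L, folds = 7L, max_iter = 200L) {
  fps <- as_fp_matrix(fps)
  n <- nrow(fps)
  if (is.null(d)) d <- pairwise_distance_matrix(fps)
  d <- as.matrix(d)
  if (is.null(candidate_counts)) {
    candidate_counts <- unique(pmax(1L, pmin(c(5L, 10L, 20L, 40L), n %/% 2L)))
  }
  candidate_counts <- sort(unique(as.integer(candidate_counts)))
  if (!length(candidate_counts)) stop("candidate_counts must be nonempty")

  cv_means <- NULL
  if (length(candidate_counts) > 1L) {
    if (n < 2L * folds) {
      stop("n = ", n, " is too small for ", folds,
           "-fold cross-validation; pass fewer folds via `folds`")
    }
    set.seed(seed)
    fold_id <- sample(rep_len(seq_len(folds), n))
    cv_means <- vapply(candidate_counts, function(k) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- which(fold_id != f)
        te <- which(fold_id == f)
        if (k >= length(tr)) return(NA_real_)
        m <- neuroscale_core(fps[tr, , drop = FALSE],
                             d[tr, tr, drop = FALSE], k,
                             seed = seed + f, max_iter = max_iter)
        y_te <- neuroscale_transform(m, fps[te, , drop = FALSE])$coords
        y_tr <- neuroscale_transform(m, fps[tr, , drop = FALSE])$coords
        heldout_stress(y_te, y_tr, d[te, , drop = FALSE], te, tr)
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    k_best <- candidate_counts[which.min(cv_means)]
  } else {
    k_best <- candidate_counts[1]
  }
  if (k_best >= n) k_best <- max(1L, n - 1L)
  model <- neuroscale_core(fps, d, k_best, seed = seed, max_iter = max_iter)
  model$cv <- if (is.null(cv_means)) NULL else
    stats::setNames(cv_means, candidate_counts)
  model
}

# stress over pairs (test i, any j) given embedded coords and target d rows
heldout_stress <- function(y_te, y_tr, d_te_all, te, tr) {
  y_all <- matrix(NA_real_, length(te) + length(tr), 2L)
  y_all[te, ] <- y_te
  y_all[tr, ] <- y_tr
  dh <- sqrt(outer(rowSums(y_te^2), rowSums(y_all^2), "+") -
               2 * y_te %*% t(y_all))
  dh[!is.finite(dh)] <- 0
  keep <- matrix(TRUE, length(te), nrow(y_all))
  keep[cbind(seq_along(te), te)] <- FALSE
  delta <- d_te_all
  denom <- sum(delta[keep]^2)
  sqrt(sum((dh[keep] - delta[keep])^2) / max(denom, 1e-300))
}

# fit with a fixed number of centers
neuroscale_core <- function(fps, d, k, seed, max_iter) {
  n <- nrow(fps)
  k <- max(1L, min(k, n - 1L))
  if (k == 1L) {
    center_idx <- which.min(rowSums(d))  # most central compound
  } else {
    center_idx <- cluster::pam(stats::as.dist(d), k = k,
                               pamonce = 2)$id.med
  }
  centers <- fps[center_idx, , drop = FALSE]
  dc <- d[, center_idx, drop = FALSE]
  width <- if (k > 1L) {
    stats::median(d[center_idx, center_idx][upper.tri(diag(k))])
  } else {
    stats::median(dc)
  }
  if (!is.finite(width) || width <= 0) width <- 0.5
  phi <- cbind(1, exp(-dc^2 / (2 * width^2)))

  # initialize the linear map by regressing onto an MDS configuration
  init <- mds_project(d, seed = seed, restarts = 2L, max_iter = 100L)
  w0 <- qr.solve(crossprod(phi) + 1e-8 * diag(ncol(phi)),
                 crossprod(phi, init$coords))

  lt <- lower.tri(d)
  denom <- sum(d[lt]^2)
  obj <- function(wv) {
    y <- phi %*% matrix(wv, ncol = 2L)
    dh <- as.matrix(stats::dist(y))
    sum((dh[lt] - d[lt])^2)
  }
  grad <- function(wv) {
    y <- phi %*% matrix(wv, ncol = 2L)
    dh <- as.matrix(stats::dist(y))
    r <- ifelse(dh > 1e-12, (dh - d) / dh, 0)
    gy <- 2 * (rowSums(r) * y - r %*% y)
    as.vector(crossprod(phi, gy))
  }
  opt <- stats::optim(as.vector(w0), obj, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  w <- matrix(opt$par, ncol = 2L)
  structure(
    list(centers = centers, center_idx = center_idx, width = width,
         weights = w, n_rbf = k,
         stress = sqrt(opt$value / max(denom, 1e-300)),
         fp_length = ncol(fps)),
    class = "neuroscale_model"
  )
}

#' Project fingerprints through a fitted Neuroscale model
#'
#' A deterministic pure function of the model and its input: Gaussian
#' RBF activations on the Tanimoto distance to each center, followed by
#' the linear output map. Identical fingerprints map to identical
#' coordinates.
#'
#' @param model A `neuroscale_model` from [neuroscale_fit()].
#' @param fps Fingerprint matrix with the training bit length.
#' @return An `embedding2d` with `method = "neuroscale"`.
#' @export
neuroscale_transform <- function(model, fps) {
  stopifnot(inherits(model, "neuroscale_model"))
  fps <- as_fp_matrix(fps)
  if (ncol(fps) != model$fp_length) {
    stop("fingerprint length ", ncol(fps),
         " does not match training length ", model$fp_length)
  }
  inter <- fps %*% t(model$centers)
  union <- outer(rowSums(fps), rowSums(model$centers), "+") - inter
  if (any(union == 0)) stop("all-zero fingerprint passed to neuroscale_transform")
  dc <- 1 - inter / union
  phi <- cbind(1, exp(-dc^2 / (2 * model$width^2)))
  structure(
    list(coords = phi %*% model$weights, stress = model$stress,
         method = "neuroscale", converged = TRUE, stress_trace = NULL),
    class = "embedding2d"
  )
}

#' Fit and apply a Neuroscale embedding in one step
#'
#' @inheritParams neuroscale_fit
#' @return An `embedding2d` for the training compounds (with the fitted
#'   model attached as attribute `"model"`).
#' @export
neuroscale_project <- function(fps, d = NULL, candidate_counts = NULL,
                               seed = 1L, folds = 7L, max_iter = 200L) {
  model <- neuroscale_fit(fps, d, candidate_counts, seed, folds, max_iter)
  e <- neuroscale_transform(model, fps)
  attr(e, "model") <- model
  e
}
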