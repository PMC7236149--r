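#' Normalized Kruskal stress of a 2D configuration
#'
#' Measures how faithfully a planar configuration reproduces a target
#' distance matrix: `sqrt(sum((dhat - d)^2) / sum(d^2))`, where `dhat`
#' are the Euclidean distances between embedded points and `d` the
#' target (Tanimoto) distances. Zero means a perfect embedding.
#'
#' @param coords Numeric `n x 2` coordinate matrix.
#' @param d Symmetric `n x n` target distance matrix.
#' @return Nonnegative scalar.
#' @export
stress <- function(coords, d) {
  coords <- as.matrix(coords)
  d <- as.matrix(d)
  n <- nrow(coords)
  if (n < 2L) stop("stress requires at least 2 points")
  if (nrow(d) != n || ncol(d) != n) {
    stop("coordinate count does not match distance matrix size")
  }
  dhat <- as.matrix(stats::dist(coords))
  lt <- lower.tri(d)
  denom <- sum(d[lt]^2)
  if (denom == 0) return(sqrt(sum(dhat[lt]^2)))
  sqrt(sum((dhat[lt] - d[lt])^2) / denom)
}

#' Metric multidimensional scaling by SMACOF stress majorization
#'
#' Embeds a Tanimoto distance matrix in the plane by iterative stress
#' majorization (the Guttman transform), which guarantees a
#' monotonically non-increasing raw stress across iterations. Several
#' random restarts are run and the configuration with the lowest final
#' stress is returned; results are deterministic for a given seed.
#'
#' @param d Symmetric distance matrix with zero diagonal, `n >= 3`.
#' @param seed Integer seed controlling the random initializations.
#' @param restarts Number of random restarts (default 4).
#' @param max_iter Maximum majorization iterations per restart.
#' @param tol Relative raw-stress decrease below which iteration stops.
#' @return An `embedding2d` object: list with `coords` (`n x 2`),
#'   `stress` (normalized Kruskal stress), `method = "mds"`,
#'   `converged` flag, and `stress_trace` (per-iteration normalized
#'   stress of the winning restart).
#' @examples
#' pts <- matrix(rnorm(20), ncol = 2)
#' e <- mds_project(as.matrix(dist(pts)), seed = 1)
#' e$stress  # ~0: exact 2D configuration is recoverable
#' @export
mds_project <- function(d, seed = 1L, restarts = 4L, max_iter = 300L,
                        tol = 1e-6) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("mds_project requires at least 3 points")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    x <- matrix(stats::rnorm(n * 2L), n, 2L) * max(stats::sd(d), 1e-8)
    res <- smacof_run(x, d, max_iter, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  structure(
    list(coords = best$coords, stress = best$stress, method = "mds",
         converged = best$converged, stress_trace = best$trace),
    class = "embedding2d"
  )
}

# one SMACOF run from a given start configuration
smacof_run <- function(x, d, max_iter, tol) {
  n <- nrow(d)
  lt <- lower.tri(d)
  denom <- sum(d[lt]^2)
  raw <- function(x) {
    dh <- as.matrix(stats::dist(x))
    sum((dh[lt] - d[lt])^2)
  }
  s_prev <- raw(x)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dh <- as.matrix(stats::dist(x))
    ratio <- ifelse(dh > 1e-12, d / dh, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n  # Guttman transform
    s_cur <- raw(x)
    trace <- c(trace, sqrt(s_cur / max(denom, 1e-300)))
    # absolute floor: exactly embeddable data decays geometrically and
    # would never satisfy a purely relative criterion
    if (s_cur < 1e-12 * max(denom, 1e-300) ||
        s_prev - s_cur < tol * max(s_prev, 1e-300)) {
      converged <- TRUE
      break
    }
    s_prev <- s_cur
  }
  if (!converged) {
    warning("SMACOF did not converge within ", max_iter,
            " iterations; returning best configuration")
  }
  list(coords = x, stress = sqrt(raw(x) / max(denom, 1e-300)),
       converged = converged, trace = trace)
}

#' Canonically orient a 2D embedding
#'
#' Embeddings from stress minimization are defined only up to
#' translation, rotation and reflection. This fixes a reference frame so
#' that azimuth viewing angles are comparable across landscapes: the
#' configuration is centered on its centroid, rotated to its principal
#' axes (largest variance along x), and reflections are resolved by
#' requiring a nonnegative third central moment (skewness) of x and y
#' (falling back to the sign of the maximum-coordinate point when a
#' moment vanishes). Idempotent, and invariant under any input rotation,
#' reflection or translation.
#'
#' @param e An `embedding2d` or a bare `n x 2` coordinate matrix.
#' @return Object of the same kind with canonically oriented `coords`.
#' @export
canonical_orient <- function(e) {
  coords <- if (inherits(e, "embedding2d")) e$coords else as.matrix(e)
  x <- sweep(coords, 2L, colMeans(coords))
  if (all(abs(x) < 1e-12)) {
    warning("degenerate embedding (all points identical); returned unchanged")
    return(e)
  }
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  x <- x %*% ev$vectors
  for (j in 1:2) {
    m3 <- mean(x[, j]^3)
    s <- if (abs(m3) > 1e-10 * max(mean(x[, j]^2), 1e-300)^1.5) {
      sign(m3)
    } else {
      sign(x[which.max(abs(x[, j])), j])
    }
    if (s < 0) x[, j] <- -x[, j]
  }
  if (inherits(e, "embedding2d")) {
    e$coords <- x
    e
  } else {
    x
  }
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %s: %d points, stress %.4g\n",
              x$method, nrow(x$coords), x$stress))
  invisible(x)
}

#' Write an embedding to CSV
#' @param e An `embedding2d`.
#' @param path Output path.
#' @param ids Optional compound ids (recycled row names otherwise).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(e, path, ids = NULL) {
  stopifnot(inherits(e, "embedding2d"))
  if (is.null(ids)) ids <- seq_len(nrow(e$coords))
  utils::write.csv(
    data.frame(id = ids, x = e$coords[, 1], y = e$coords[, 2],
               method = e$method, stress = e$stress),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
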