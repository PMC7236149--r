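#' Fit a Gaussian process to potencies over a 2D embedding
#'
#' Interpolates the potency hyper-surface of an activity landscape:
#' given the 2D embedding coordinates of the compounds and their pKi
#' potencies, fits a Gaussian process with a squared-exponential
#' (Gaussian) kernel plus white noise,
#' `k(x, x') = s2 * exp(-||x - x'||^2 / (2 l^2)) + n2 * I`.
#' Hyperparameters `(s2, l, n2)` are obtained by maximizing the log
#' marginal likelihood (L-BFGS-B on the log scale, with bound
#' constraints and multiple seeded restarts); the prior mean is the
#' sample mean potency. Singular kernel matrices trigger jitter
#' escalation before failing.
#'
#' @param coords `n x 2` coordinate matrix or an `embedding2d`.
#' @param potencies Numeric pKi values, one per row of `coords`.
#' @param restarts Number of optimizer restarts (default 3).
#' @param noise_bounds Bounds for the noise variance (pKi^2); the lower
#'   bound acts as jitter so that noise-free data remain interpolable.
#' @param seed Integer seed for restart initializations.
#' @return A `gp_model`: list with `coords`, `y`, hyperparameters
#'   `signal_variance`, `length_scale`, `noise_variance`, prior `mean`,
#'   the Cholesky factor and precomputed weights for prediction.
#' @seealso [gpr_predict()], [gpr_surface()]
#' @export
gpr_fit <- function(coords, potencies, restarts = 3L,
                    noise_bounds = c(1e-6, 4), seed = 1L) {
  if (inherits(coords, "embedding2d")) coords <- coords$coords
  coords <- as.matrix(coords)
  y <- as.numeric(potencies)
  n <- nrow(coords)
  if (n < 3L) stop("gpr_fit requires at least 3 points")
  if (length(y) != n) stop("coords and potencies lengths differ")
  if (any(!is.finite(coords)) || any(!is.finite(y))) {
    stop("non-finite coordinates or potencies")
  }
  mu <- mean(y)
  yc <- y - mu
  d2 <- as.matrix(stats::dist(coords))^2
  vy <- max(stats::var(y), 1e-10)
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1

  # objective: negative log marginal likelihood over log(s2, l, n2)
  nll <- function(par) {
    s2 <- exp(par[1]); l <- exp(par[2]); n2 <- exp(par[3])
    kmat <- s2 * exp(-d2 / (2 * l^2))
    diag(kmat) <- diag(kmat) + n2
    ch <- tryCatch(chol(kmat), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  lower <- log(c(1e-4 * vy, med / 20, noise_bounds[1]))
  upper <- log(c(100 * vy, med * 20, noise_bounds[2]))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- log(c(vy, med, 0.05 * vy)) +
      (if (r > 1) stats::rnorm(3, 0, 0.7) else 0)
    init <- pmin(pmax(init, lower), upper)
    opt <- tryCatch(
      stats::optim(init, nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  s2 <- exp(best$par[1]); l <- exp(best$par[2]); n2 <- exp(best$par[3])

  kmat <- s2 * exp(-d2 / (2 * l^2))
  jitter <- 0
  ch <- NULL
  repeat {
    ch <- tryCatch(chol(kmat + diag(n2 + jitter, n)), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
    if (jitter > 1e-2) stop("kernel matrix is numerically singular")
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(
    list(coords = coords, y = y, mean = mu,
         signal_variance = s2, length_scale = l, noise_variance = n2,
         chol = ch, alpha = alpha,
         log_marginal = -best$value),
    class = "gp_model"
  )
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(paste0("<gp_model> n=%d  signal_var=%.3g  length_scale=%.3g",
                     "  noise_var=%.3g\n"),
              length(x$y), x$signal_variance, x$length_scale,
              x$noise_variance))
  invisible(x)
}

#' Posterior mean prediction from a fitted Gaussian process
#'
#' @param model A `gp_model` from [gpr_fit()].
#' @param newcoords `m x 2` matrix of query coordinates.
#' @return Numeric vector of posterior mean potencies (pKi).
#' @export
gpr_predict <- function(model, newcoords) {
  stopifnot(inherits(model, "gp_model"))
  newcoords <- matrix(as.numeric(newcoords), ncol = 2L)
  d2 <- outer(rowSums(newcoords^2), rowSums(model$coords^2), "+") -
    2 * newcoords %*% t(model$coords)
  d2[d2 < 0] <- 0
  ks <- model$signal_variance * exp(-d2 / (2 * model$length_scale^2))
  as.numeric(model$mean + ks %*% model$alpha)
}

#' Evaluate the potency hyper-surface on a regular grid
#'
#' Evaluates the GP posterior mean on a regular `resolution x
#' resolution` grid spanning the bounding box of the training
#' coordinates, padded by 5% on each side, and attaches potency colors.
#'
#' @param model A `gp_model`.
#' @param resolution Grid nodes per axis (default 100, minimum 8).
#' @param cmap Color map from [potency_colormap()].
#' @param pad Fractional bounding-box padding per side (default 0.05).
#' @return A `surface_grid`: list with `x`, `y` (axis node positions),
#'   `z` (`resolution x resolution` pKi matrix, x indexing rows),
#'   `colors` (hex color matrix) and `cmap`.
#' @export
gpr_surface <- function(model, resolution = 100L, cmap = potency_colormap(),
                        pad = 0.05) {
  stopifnot(inherits(model, "gp_model"))
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("resolution must be at least 8")
  rngx <- range(model$coords[, 1])
  rngy <- range(model$coords[, 2])
  padx <- max(diff(rngx), 1e-9) * pad
  pady <- max(diff(rngy), 1e-9) * pad
  xs <- seq(rngx[1] - padx, rngx[2] + padx, length.out = resolution)
  ys <- seq(rngy[1] - pady, rngy[2] + pady, length.out = resolution)
  grid <- cbind(rep(xs, times = resolution), rep(ys, each = resolution))
  z <- matrix(gpr_predict(model, grid), nrow = resolution)  # z[i,j]=f(xs[i],ys[j])
  surface_grid(xs, ys, z, cmap = cmap)
}

#' Construct a surface grid object
#'
#' @param x,y Strictly increasing axis node positions.
#' @param z Matrix of pKi values, `z[i, j]` at `(x[i], y[j])`.
#' @param cmap Color map from [potency_colormap()].
#' @return A `surface_grid` with per-node colors attached.
#' @export
surface_grid <- function(x, y, z, cmap = potency_colormap()) {
  z <- as.matrix(z)
  if (length(x) != nrow(z) || length(y) != ncol(z)) {
    stop("z must be length(x) by length(y)")
  }
  if (any(!is.finite(z))) stop("surface z values must be finite")
  cols <- matrix(potency_to_color(z, cmap, hex = TRUE), nrow = nrow(z))
  structure(list(x = x, y = y, z = z, colors = cols, cmap = cmap),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes, pKi %.2f .. %.2f\n",
              nrow(x$z), ncol(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Write a surface grid to CSV (long format) with a JSON sidecar
#' @param s A `surface_grid`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @param model Optional `gp_model` whose hyperparameters go into the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path, model = NULL) {
  stopifnot(inherits(s, "surface_grid"))
  df <- data.frame(x = rep(s$x, times = length(s$y)),
                   y = rep(s$y, each = length(s$x)),
                   z = as.vector(s$z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(resolution = dim(s$z),
               anchors = list(green = s$cmap$green, yellow = s$cmap$mid,
                              red = s$cmap$red))
  if (!is.null(model)) {
    meta$gp <- list(signal_variance = model$signal_variance,
                    length_scale = model$length_scale,
                    noise_variance = model$noise_variance,
                    mean = model$mean)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- potency color gradient ------------------------------------------------

#' Potency color map (green over yellow to red)
#'
#' The fixed potency color coding of the landscapes: pKi of
#' `green` (default 5.75) and below maps to pure green, `red` (default
#' 8.75) and above to pure red. With `style = "gradient"` (default) the
#' color varies piecewise-linearly from green to yellow over
#' `[green, mid]` and yellow to red over `[mid, red]`, `mid` defaulting
#' to the midpoint 7.25. With `style = "band"` the whole interior range
#' is flat yellow.
#'
#' @param green,red Anchor potencies (pKi) for pure green / pure red.
#' @param mid Potency of pure yellow (gradient style only).
#' @param style `"gradient"` or `"band"`.
#' @return A `potency_colormap` object.
#' @export
potency_colormap <- function(green = 5.75, red = 8.75,
                             mid = (green + red) / 2,
                             style = c("gradient", "band")) {
  style <- match.arg(style)
  if (!(green < mid && mid < red)) stop("need green < mid < red")
  structure(list(green = green, mid = mid, red = red, style = style),
            class = "potency_colormap")
}

#' Map potencies to colors
#'
#' @param p Numeric pKi values (any shape).
#' @param cmap A [potency_colormap()].
#' @param hex If `TRUE` return hex color strings, else an `n x 3` RGB
#'   matrix in `[0, 1]`.
#' @return Colors, one per element of `p`.
#' @examples
#' potency_to_color(c(5.75, 7.25, 8.75), hex = FALSE)
#' @export
potency_to_color <- function(p, cmap = potency_colormap(), hex = FALSE) {
  stopifnot(inherits(cmap, "potency_colormap"))
  p <- as.numeric(p)
  if (any(!is.finite(p))) stop("potencies must be finite")
  if (cmap$style == "band") {
    r <- ifelse(p >= cmap$red, 1, ifelse(p > cmap$green, 1, 0))
    g <- ifelse(p <= cmap$green, 1, ifelse(p < cmap$red, 1, 0))
  } else {
    # green (0,1,0) -> yellow (1,1,0) -> red (1,0,0)
    t1 <- pmin(pmax((p - cmap$green) / (cmap$mid - cmap$green), 0), 1)
    t2 <- pmin(pmax((p - cmap$mid) / (cmap$red - cmap$mid), 0), 1)
    r <- t1
    g <- 1 - t2
  }
  rgbmat <- cbind(r = r, g = g, b = 0)
  if (hex) grDevices::rgb(rgbmat[, 1], rgbmat[, 2], rgbmat[, 3]) else rgbmat
}
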