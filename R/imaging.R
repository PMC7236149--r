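#' Construct a rendered-image object
#'
#' Thin container pairing a pixel array with landscape provenance
#' metadata. Pixels are stored in `[0, 1]`, as an `H x W x 3` array for
#' color images or an `H x W` matrix for single-channel variants
#' (grayscale, black/white, edge maps).
#'
#' @param pixels Numeric array (`H x W x 3`) or matrix (`H x W`).
#' @param meta Named list; recognized fields: `class`, `variant`,
#'   `projection`, `azimuth`, `elevation`, `encoding`.
#' @return An `al_image` object.
#' @export
al_image <- function(pixels, meta = list()) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L))) {
    stop("pixels must be an H x W matrix or an H x W x C array")
  }
  defaults <- list(class = NA_character_, variant = NA_character_,
                   projection = NA_character_, azimuth = NA_real_,
                   elevation = NA_real_, encoding = "color")
  meta <- utils::modifyList(defaults, meta)
  structure(list(pixels = pixels, meta = meta), class = "al_image")
}

#' @export
print.al_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<al_image> %d x %d x %d  [%s] %s/%s az=%s el=%s\n",
              d[1], d[2], if (length(d) == 3L) d[3] else 1L,
              x$meta$encoding, x$meta$class, x$meta$variant,
              format(x$meta$azimuth), format(x$meta$elevation)))
  invisible(x)
}

#' Viewpoint specification
#'
#' The systematic view grid of the imaging protocol uses azimuth angles
#' 0/90/180/270 degrees and elevation angles 0/35/65/90 degrees; other
#' angles are permitted for exploration.
#'
#' @param azimuth Horizontal rotation in degrees.
#' @param elevation Vertical tilt in degrees (0 = profile view, 90 =
#'   top-down view).
#' @return A `view_spec` list.
#' @export
view_spec <- function(azimuth = 0, elevation = 35) {
  stopifnot(is.finite(azimuth), is.finite(elevation),
            elevation >= 0, elevation <= 90)
  structure(list(azimuth = azimuth, elevation = elevation),
            class = "view_spec")
}

#' Standard view grids
#' @return Numeric vector of the default azimuth or elevation angles.
#' @export
default_azimuths <- function() c(0, 90, 180, 270)

#' @rdname default_azimuths
#' @export
default_elevations <- function() c(0, 35, 65, 90)

#' Render a 3D activity landscape view to an image
#'
#' Renders the potency hyper-surface off-screen with the base
#' perspective renderer: white background, no axes or box, surface
#' facets colored by the potency color gradient, viewpoint set by the
#' azimuth/elevation pair. Identical inputs give pixel-identical output.
#'
#' @param surface A `surface_grid`.
#' @param view A [view_spec()].
#' @param width,height Output resolution in pixels (defaults 1200 x
#'   800).
#' @param zlim Potency axis limits; defaults to the surface range.
#'   Sharing `zlim` across the variants of one class keeps their
#'   vertical relief comparable.
#' @param expand `persp` vertical expansion factor.
#' @param meta Metadata list stored in the result.
#' @param file Optional path; when given the PNG is written there (and
#'   still returned in memory).
#' @return An `al_image` with `H x W x 3` pixels in `[0, 1]`.
#' @export
render_landscape <- function(surface, view = view_spec(),
                             width = 1200L, height = 800L,
                             zlim = NULL, expand = 0.6,
                             meta = list(), file = NULL) {
  stopifnot(inherits(surface, "surface_grid"), inherits(view, "view_spec"))
  if (is.null(zlim)) zlim <- range(surface$z)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  z <- surface$z
  nx <- nrow(z); ny <- ncol(z)
  zf <- (z[-1, -1] + z[-nx, -1] + z[-1, -ny] + z[-nx, -ny]) / 4
  cols <- matrix(potency_to_color(zf, surface$cmap, hex = TRUE),
                 nrow = nx - 1L)
  out <- if (is.null(file)) tempfile(fileext = ".png") else file
  grDevices::png(out, width = width, height = height)
  graphics::par(mar = c(0, 0, 0, 0), bg = "white")
  ok <- tryCatch({
    graphics::persp(surface$x, surface$y, z,
                    theta = view$azimuth, phi = view$elevation,
                    col = cols, border = NA, box = FALSE, axes = FALSE,
                    expand = expand, zlim = zlim, scale = TRUE)
    TRUE
  }, finally = grDevices::dev.off())
  px <- png::readPNG(out)
  if (is.null(file)) unlink(out)
  if (length(dim(px)) == 3L) px <- px[, , 1:3, drop = FALSE]
  meta$azimuth <- view$azimuth
  meta$elevation <- view$elevation
  meta$encoding <- "color"
  al_image(px, meta)
}

#' Crop an image to its content and resize to the feature resolution
#'
#' Crops to the bounding box of non-background (non-white) pixels,
#' padded by a fraction of the box size, then resizes to the fixed
#' feature resolution (default 360 x 220, aspect ratio not preserved)
#' by bilinear interpolation. A fixed fractional crop box may be given
#' instead of the adaptive rule.
#'
#' @param img An `al_image` (color or single-channel).
#' @param width,height Target resolution (defaults 360 x 220).
#' @param crop `"auto"` (content bounding box) or a fractional box
#'   `c(row0, col0, row1, col1)` in `[0, 1]`.
#' @param pad Fractional padding of the bounding box per side.
#' @param background Intensity at or above which a pixel counts as
#'   background in every channel.
#' @return An `al_image` of size `height x width`.
#' @export
crop_resize <- function(img, width = 360L, height = 220L, crop = "auto",
                        pad = 0.02, background = 0.995) {
  stopifnot(inherits(img, "al_image"))
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (identical(crop, "auto")) {
    fg <- if (length(dim(px)) == 3L) {
      apply(px < background, c(1, 2), any)
    } else {
      px < background
    }
    if (!any(fg)) stop("cannot crop a fully-background image")
    rr <- range(which(rowSums(fg) > 0))
    cc <- range(which(colSums(fg) > 0))
    pr <- max(1L, ceiling((rr[2] - rr[1] + 1L) * pad))
    pc <- max(1L, ceiling((cc[2] - cc[1] + 1L) * pad))
    rows <- max(1L, rr[1] - pr):min(h, rr[2] + pr)
    cols <- max(1L, cc[1] - pc):min(w, cc[2] + pc)
  } else {
    stopifnot(is.numeric(crop), length(crop) == 4L)
    rows <- max(1L, floor(crop[1] * h)):min(h, ceiling(crop[3] * h))
    cols <- max(1L, floor(crop[2] * w)):min(w, ceiling(crop[4] * w))
  }
  cropped <- if (length(dim(px)) == 3L) {
    px[rows, cols, , drop = FALSE]
  } else {
    px[rows, cols, drop = FALSE]
  }
  resized <- EBImage::resize(cropped, w = height, h = width,
                             filter = "bilinear")
  resized <- if (length(dim(px)) == 3L) {
    array(as.numeric(resized), dim = c(height, width, dim(px)[3]))
  } else {
    matrix(as.numeric(resized), nrow = height)
  }
  resized[resized < 0] <- 0
  resized[resized > 1] <- 1
  al_image(resized, img$meta)
}

#' Convert a color image to grayscale
#'
#' Weighted channel sum `0.299 R + 0.587 G + 0.114 B` (the standard
#' luma weights).
#'
#' @param img An `al_image` with 3 channels.
#' @return A single-channel `al_image` with `encoding = "grayscale"`.
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "al_image"))
  px <- img$pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("to_grayscale expects a 3-channel image")
  }
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  meta <- img$meta
  meta$encoding <- "grayscale"
  al_image(g, meta)
}

#' Binarize a grayscale image by Otsu's threshold
#'
#' Intensities are quantized to 256 levels; the threshold maximizing
#' the between-class variance of the resulting histogram is selected
#' (pixels at or below the threshold become 0, above become 1). For a
#' constant image no separation exists: all pixels map to 0 and the
#' constant level is reported as the threshold.
#'
#' @param img Single-channel `al_image` with intensities in `[0, 1]`.
#' @return List with `threshold` (on the 0-255 level scale) and `bw`
#'   (an `al_image` with values in `{0, 1}` and `encoding = "bw"`).
#' @export
otsu_binarize <- function(img) {
  stopifnot(inherits(img, "al_image"), is.matrix(img$pixels))
  q <- round(pmin(pmax(img$pixels, 0), 1) * 255)
  meta <- img$meta
  meta$encoding <- "bw"
  if (min(q) == max(q)) {
    return(list(threshold = min(q),
                bw = al_image(matrix(0, nrow(q), ncol(q)), meta)))
  }
  counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                    # P(class0) for t = 0..255
  mu_cum <- cumsum(p * levels)
  mu_tot <- mu_cum[256]
  # between-class variance for threshold t (class0: <= t), t = 0..254
  w0t <- w0[1:255]
  mu0t <- mu_cum[1:255]
  bcv <- ifelse(w0t > 0 & w0t < 1,
                (mu_tot * w0t - mu0t)^2 / (w0t * (1 - w0t)), 0)
  # ties (flat plateau of maximal variance, e.g. exactly bimodal data):
  # take the plateau midpoint so the threshold sits between the modes
  at_max <- which(bcv >= max(bcv) * (1 - 1e-12))
  t <- levels[floor(mean(range(at_max)))]
  list(threshold = t, bw = al_image((q > t) * 1, meta))
}

#' Printed Sobel convolution matrices
#' @return List with `Gx` and `Gy` 3 x 3 matrices.
#' @export
sobel_kernels <- function() {
  list(Gx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE),
       Gy = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE))
}

#' Sobel edge response (vertical gradient operator)
#'
#' Convolves the image with the vertical Sobel matrix `Gy`
#' (`[-1,-2,-1; 0,0,0; 1,2,1]`), takes the absolute response and
#' rescales to `[0, 1]`; borders are handled by edge replication.
#'
#' @param img Single-channel `al_image` (at least 3 x 3).
#' @param rescale If `FALSE` return the raw absolute response.
#' @return An `al_image` with `encoding = "sobel"`.
#' @export
sobel_edges <- function(img, rescale = TRUE) {
  stopifnot(inherits(img, "al_image"), is.matrix(img$pixels))
  if (any(dim(img$pixels) < 3L)) stop("image must be at least 3 x 3")
  r <- abs(conv3_replicate(img$pixels, sobel_kernels()$Gy))
  r[r < 1e-10] <- 0   # kill floating-point residue on flat regions
  if (rescale && max(r) > 0) r <- r / max(r)
  meta <- img$meta
  meta$encoding <- "sobel"
  al_image(r, meta)
}

# 3x3 correlation with edge replication (sign-symmetric with convolution
# under abs for the Sobel kernels, whose 180-degree rotation is their
# negative)
conv3_replicate <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  mp <- m[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (di in -1:1) {
    for (dj in -1:1) {
      out <- out + k[di + 2, dj + 2] *
        mp[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
    }
  }
  out
}

#' Canny edge detection
#'
#' Multi-stage edge detector on an 8-bit-quantized grayscale image:
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along
#' the quantized gradient direction, and double-threshold hysteresis
#' (weak edge segments survive only when 8-connected to a strong
#' pixel). Thresholds are on the 0-255 gradient magnitude scale.
#'
#' @param img Single-channel `al_image`.
#' @param low,high Hysteresis thresholds, `low < high` (defaults
#'   100/200).
#' @param sigma Standard deviation of the smoothing Gaussian in pixels.
#' @return Binary `al_image` with `encoding = "canny"`.
#' @export
canny_edges <- function(img, low = 100, high = 200, sigma = 1) {
  stopifnot(inherits(img, "al_image"), is.matrix(img$pixels))
  if (low >= high) stop("canny_edges requires low < high")
  m <- round(pmin(pmax(img$pixels, 0), 1) * 255)
  h <- nrow(m); w <- ncol(m)
  if (h < 5L || w < 5L) stop("image too small for Canny detection")
  if (sigma > 0) {
    # replicate-pad before smoothing: the FFT-based blur is circular and
    # would otherwise manufacture edges where opposite borders differ
    r <- ceiling(2 * sigma)
    mp <- m[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
    mp <- EBImage::gblur(mp, sigma = sigma, radius = 2 * r + 1)
    m <- matrix(as.numeric(mp), h + 2 * r, w + 2 * r)[(r + 1):(r + h),
                                                      (r + 1):(r + w)]
  }
  ker <- sobel_kernels()
  gx <- conv3_replicate(m, ker$Gx)
  gy <- conv3_replicate(m, ker$Gy)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  dir <- ifelse(ang < 22.5 | ang >= 157.5, 1L,        # horizontal gradient
                ifelse(ang < 67.5, 2L,                # diagonal /
                       ifelse(ang < 112.5, 3L, 4L)))  # vertical, diagonal \

  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mag
  shift <- function(di, dj) pad[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  n1 <- matrix(0, h, w); n2 <- n1
  sel <- dir == 1L; n1[sel] <- shift(0, -1)[sel]; n2[sel] <- shift(0, 1)[sel]
  sel <- dir == 2L; n1[sel] <- shift(-1, 1)[sel]; n2[sel] <- shift(1, -1)[sel]
  sel <- dir == 3L; n1[sel] <- shift(-1, 0)[sel]; n2[sel] <- shift(1, 0)[sel]
  sel <- dir == 4L; n1[sel] <- shift(-1, -1)[sel]; n2[sel] <- shift(1, 1)[sel]
  # strict comparison on one side breaks the tie when the maximum is
  # shared by two neighboring pixels (symmetric step), keeping the edge
  # one pixel wide
  nms <- mag * (mag > n1 & mag >= n2)

  strong <- nms >= high
  weak <- nms >= low
  edges <- matrix(0, h, w)
  if (any(strong)) {
    lab <- EBImage::bwlabel(weak)
    keep <- unique(lab[strong])
    keep <- keep[keep > 0]
    edges[lab %in% keep] <- 1
  }
  meta <- img$meta
  meta$encoding <- "canny"
  al_image(edges, meta)
}

#' Flatten a single-channel image into the standard feature vector
#'
#' Scales intensities to `[0, 1]` (values above 1 are interpreted as
#' 8-bit and divided by 255) and flattens row-major: pixel `(r, c)`
#' (0-based) lands at index `r * W + c`. At the standard 360 x 220
#' feature resolution this yields 79,200 features.
#'
#' @param img Single-channel `al_image`, `height x width` = 220 x 360
#'   unless `check_dims = FALSE`.
#' @param check_dims Enforce the standard feature resolution.
#' @return Numeric feature vector of length `height * width`.
#' @export
normalize_and_flatten <- function(img, check_dims = TRUE) {
  stopifnot(inherits(img, "al_image"))
  if (!is.matrix(img$pixels)) {
    stop("normalize_and_flatten expects a single-channel image")
  }
  m <- img$pixels
  if (check_dims && !(nrow(m) == 220L && ncol(m) == 360L)) {
    stop("expected a 220 x 360 image; got ", nrow(m), " x ", ncol(m))
  }
  if (max(m) > 1) m <- m / 255
  m[m < 0] <- 0
  as.vector(t(m))
}

#' Apply an encoding variant to a cropped color image
#'
#' Runs the fixed variant pipeline on a crop-resized color image:
#' `color` returns the input; `grayscale` applies the luma conversion;
#' `bw` additionally binarizes by Otsu's threshold; `sobel` and `canny`
#' apply the respective edge detector to the grayscale image.
#'
#' @param img Color `al_image` (already crop-resized).
#' @param encoding One of `"color"`, `"grayscale"`, `"bw"`, `"sobel"`,
#'   `"canny"`.
#' @param canny_low,canny_high Canny hysteresis thresholds.
#' @return An `al_image` of the requested encoding.
#' @export
encode_variant <- function(img, encoding = c("color", "grayscale", "bw",
                                             "sobel", "canny"),
                           canny_low = 100, canny_high = 200) {
  encoding <- match.arg(encoding)
  if (encoding == "color") return(img)
  g <- to_grayscale(img)
  switch(encoding,
         grayscale = g,
         bw = otsu_binarize(g)$bw,
         sobel = sobel_edges(g),
         canny = canny_edges(g, canny_low, canny_high))
}

#' Write an image to a PNG file
#' @param img An `al_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "al_image"))
  png::writePNG(img$pixels, path)
  invisible(path)
}

#' Read an image written by [write_image()]
#' @param path PNG path.
#' @param meta Metadata to attach.
#' @return An `al_image`.
#' @export
read_image <- function(path, meta = list()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1] else px <- px[, , 1:3, drop = FALSE]
  }
  al_image(px, meta)
}
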