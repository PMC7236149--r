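# rendering at reduced resolution keeps these tests fast; the sizes the
# renderer produces scale exactly with the requested resolution

test_that("rendering produces deterministic full-color frames", {
  s <- demo_surface(n_peaks = 2)
  img <- render_landscape(s, view_spec(90, 35), width = 300, height = 200)
  expect_equal(dim(img$pixels), c(200L, 300L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  img2 <- render_landscape(s, view_spec(90, 35), width = 300, height = 200)
  expect_identical(img$pixels, img2$pixels)
  expect_equal(img$meta$azimuth, 90)
  expect_equal(img$meta$elevation, 35)
})

test_that("a constant surface renders in a single surface color", {
  flat <- generate_surface_fixture(surface_fixture_spec(n_peaks = 0,
                                                        base = 7.25))
  img <- render_landscape(flat, view_spec(0, 65), width = 240, height = 160)
  px <- matrix(img$pixels, ncol = 3)
  fg <- px[, 1] < 0.99 | px[, 2] < 0.99 | px[, 3] < 0.99
  expect_gt(sum(fg), 0)
  cols <- unique(round(px[fg, , drop = FALSE], 2))
  expect_lte(nrow(cols), 2)  # surface color (antialiased edges excluded)
})

test_that("crop_resize reaches the standard feature resolution", {
  s <- demo_surface()
  img <- render_landscape(s, view_spec(0, 35), width = 300, height = 200)
  cc <- crop_resize(img)
  expect_equal(dim(cc$pixels), c(220L, 360L, 3L))
  # uniform image stays uniform through a fixed crop + resize
  uni <- al_image(array(0.4, c(60, 90, 3)))
  out <- crop_resize(uni, crop = c(0.1, 0.1, 0.9, 0.9))
  expect_equal(range(out$pixels), c(0.4, 0.4), tolerance = 1e-6)
  expect_error(crop_resize(al_image(array(1, c(20, 20, 3)))),
               "fully-background")
})

test_that("grayscale conversion uses the printed luma weights", {
  mk <- function(r, g, b) al_image(array(rep(c(r, g, b), each = 4),
                                         c(2, 2, 3)))
  expect_equal(unique(as.vector(to_grayscale(mk(1, 0, 0))$pixels)), 0.299)
  expect_equal(unique(as.vector(to_grayscale(mk(0, 1, 0))$pixels)), 0.587)
  expect_equal(unique(as.vector(to_grayscale(mk(0, 0, 1))$pixels)), 0.114)
  expect_equal(unique(as.vector(to_grayscale(mk(1, 1, 1))$pixels)), 1)
  expect_error(to_grayscale(gray_image(matrix(0.5, 4, 4))), "3-channel")
})

test_that("otsu threshold maximizes between-class variance (oracle)", {
  otsu_oracle <- function(q) {
    counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
    n <- sum(counts)
    v <- rep(-1, 255)
    for (t in 0:254) {
      n0 <- sum(counts[1:(t + 1)])
      n1 <- n - n0
      if (n0 == 0L || n1 == 0L) next
      mu0 <- sum(counts[1:(t + 1)] * (0:t)) / n0
      mu1 <- sum(counts[(t + 2):256] * ((t + 1):255)) / n1
      v[t + 1] <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    # plateau of maximal variance -> midpoint (matches the documented
    # tie convention)
    at_max <- which(v >= max(v) * (1 - 1e-12))
    floor(mean(range(at_max))) - 1L
  }
  set.seed(31)
  for (i in 1:100) {
    q <- matrix(sample(0:255, 64, replace = TRUE,
                       prob = runif(256)^2), 8, 8)
    res <- otsu_binarize(gray_image(q / 255))
    expect_equal(res$threshold, otsu_oracle(q))
    expect_true(all(res$bw$pixels %in% c(0, 1)))
    expect_true(all((q > res$threshold) == (res$bw$pixels == 1)))
  }
})

test_that("otsu separates a bimodal image and degrades gracefully", {
  bi <- gray_image(matrix(rep(c(0, 1), each = 32), 8, 8))
  res <- otsu_binarize(bi)
  expect_gt(res$threshold, 0)
  expect_lt(res$threshold, 255)
  expect_equal(sort(unique(as.vector(res$bw$pixels))), c(0, 1))
  flat <- otsu_binarize(gray_image(matrix(0.5, 6, 6)))
  expect_equal(flat$threshold, 128)
  expect_true(all(flat$bw$pixels == 0))
})

test_that("sobel response matches direct convolution with the printed Gy", {
  gy <- sobel_kernels()$Gy
  expect_equal(gy, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE))
  conv_oracle <- function(m, k) {
    h <- nrow(m); w <- ncol(m)
    mp <- m[c(1, 1:h, h), c(1, 1:w, w)]   # replicate borders
    out <- matrix(0, h, w)
    for (i in 1:h) {
      for (j in 1:w) {
        out[i, j] <- sum(k * mp[i:(i + 2), j:(j + 2)])
      }
    }
    out
  }
  set.seed(17)
  for (rep_i in 1:5) {
    m <- matrix(runif(256), 16, 16)
    got <- sobel_edges(gray_image(m), rescale = FALSE)$pixels
    expect_equal(got, abs(conv_oracle(m, gy)), tolerance = 1e-9)
  }
  # constant image: zero response everywhere
  expect_true(all(sobel_edges(gray_image(matrix(0.3, 8, 8)))$pixels == 0))
  # vertical step (column-wise change) is invisible to Gy
  vstep <- matrix(rep(c(0, 0, 1, 1), each = 8), 8, 4)
  expect_true(all(sobel_edges(gray_image(vstep),
                              rescale = FALSE)$pixels == 0))
  # horizontal step of height h gives interior response 4h at the edge rows
  h_step <- 0.4
  hstep <- matrix(rep(c(0, 0, 0, h_step, h_step, h_step), times = 8), 6, 8)
  resp <- sobel_edges(gray_image(hstep), rescale = FALSE)$pixels
  expect_equal(unique(resp[3, 2:7]), 4 * h_step, tolerance = 1e-12)
  expect_equal(unique(resp[4, 2:7]), 4 * h_step, tolerance = 1e-12)
})

test_that("canny finds thin connected edges and is binary", {
  expect_true(all(canny_edges(gray_image(matrix(0.7, 16, 16)))$pixels == 0))
  # horizontal step: rows 1-10 dark, rows 11-20 bright
  step <- matrix(rep(c(0, 1), each = 10), nrow = 20, ncol = 16)
  out <- canny_edges(gray_image(step), 50, 150)$pixels
  expect_true(all(out %in% c(0, 1)))
  # one-pixel-wide connected edge line along the step
  per_col <- colSums(out)
  expect_true(all(per_col[3:14] == 1))
  rows_hit <- unique(which(out == 1, arr.ind = TRUE)[, 1])
  expect_lte(diff(range(rows_hit)), 1)
  expect_error(canny_edges(gray_image(step), 200, 100), "low < high")
})

test_that("feature vectors flatten row-major to length 79200", {
  m <- matrix(runif(220 * 360), 220, 360)
  v <- normalize_and_flatten(gray_image(m))
  expect_length(v, 79200L)
  expect_equal(v[1], m[1, 1])
  expect_equal(v[361], m[2, 1])    # pixel (r=1, c=0) at index r*W = 360
  expect_equal(v[2], m[1, 2])
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(normalize_and_flatten(gray_image(matrix(0, 220, 360))),
               rep(0, 79200))
  expect_error(normalize_and_flatten(gray_image(matrix(0, 10, 10))),
               "220 x 360")
})

test_that("variant pipeline preserves metadata through each stage", {
  s <- demo_surface(n_peaks = 1)
  img <- render_landscape(s, view_spec(180, 65), width = 300, height = 200,
                          meta = list(class = "k1", variant = "rugged",
                                      projection = "mds"))
  cc <- crop_resize(img)
  for (enc in c("grayscale", "bw", "sobel", "canny")) {
    out <- encode_variant(cc, enc)
    expect_equal(out$meta$class, "k1")
    expect_equal(out$meta$variant, "rugged")
    expect_equal(out$meta$projection, "mds")
    expect_equal(out$meta$azimuth, 180)
    expect_equal(out$meta$elevation, 65)
    expect_equal(out$meta$encoding, enc)
    expect_true(is.matrix(out$pixels))
  }
})

test_that("edge content increases with the number of planted peaks", {
  # top-down view: edge content reflects the potency pattern alone (at
  # oblique views the surface silhouette dominates the strongest edges)
  edge_frac <- function(k) {
    s <- generate_surface_fixture(surface_fixture_spec(
      grid_size = 48, n_peaks = k, amplitudes = 2.5, widths = 0.05,
      seed = 23
    ))
    img <- render_landscape(s, view_spec(45, 90), width = 300, height = 200,
                            zlim = c(5, 10))
    g <- to_grayscale(crop_resize(img, crop = c(0.05, 0.05, 0.95, 0.95)))
    e <- sobel_edges(g, rescale = FALSE)$pixels
    mean(e > max(e) / 2)
  }
  fracs <- vapply(c(0, 1, 4, 9), edge_frac, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("surface fixtures plant the requested number of local maxima", {
  for (k in c(0L, 3L, 5L)) {
    s <- generate_surface_fixture(surface_fixture_spec(
      grid_size = 40, n_peaks = k, widths = 0.04, seed = 2
    ))
    z <- s$z
    n <- nrow(z)
    is_max <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
        is_max[i, j] <- z[i, j] > max(nb[-5])
      }
    }
    expect_equal(sum(is_max), k)
  }
  s1 <- generate_surface_fixture(surface_fixture_spec(seed = 7))
  s2 <- generate_surface_fixture(surface_fixture_spec(seed = 7))
  expect_identical(s1$z, s2$z)
})
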