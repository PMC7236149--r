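test_that("stress matches a hand evaluation and detects exact embeddings", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  expect_equal(stress(pts, d), 0)
  expect_gt(stress(pts * 2, d), 0)
  # 3-point hand computation
  coords <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  target <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3, 3)
  dhat <- c(1, 1, sqrt(2))       # pairs (1,2), (1,3), (2,3)
  dtar <- c(2, 1, 1)
  expect_equal(stress(coords, target),
               sqrt(sum((dhat - dtar)^2) / sum(dtar^2)))
  expect_error(stress(coords[1, , drop = FALSE], matrix(0, 1, 1)),
               "at least 2")
})

test_that("MDS recovers planted planar configurations", {
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2)
  d <- as.matrix(dist(pts))
  e <- mds_project(d, seed = 1)
  expect_lt(e$stress, 1e-4)
  pr <- vegan::procrustes(pts, e$coords, symmetric = TRUE)
  expect_lt(sqrt(pr$ss), 1e-3)
})

test_that("MDS is deterministic and monotone in stress", {
  d <- pairwise_distance_matrix(rand_fps(15, seed = 4))
  e1 <- suppressWarnings(mds_project(d, seed = 7))
  e2 <- suppressWarnings(mds_project(d, seed = 7))
  expect_identical(e1$coords, e2$coords)
  expect_true(all(diff(e1$stress_trace) <= 1e-9))
  # equilateral triangle embeds exactly
  tri <- matrix(1, 3, 3) - diag(3)
  expect_lt(suppressWarnings(mds_project(tri, seed = 1))$stress, 1e-4)
})

test_that("canonical orientation is idempotent and invariant to isometries", {
  set.seed(5)
  base <- matrix(rnorm(30), ncol = 2)
  canon <- canonical_orient(base)
  expect_equal(colMeans(canon), c(0, 0), tolerance = 1e-12)
  expect_equal(canonical_orient(canon), canon, tolerance = 1e-8)
  for (ang in c(0.3, 1.2, 2.9)) {
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    moved <- base %*% rot
    moved[, 1] <- moved[, 1] + 5          # translation
    expect_equal(canonical_orient(moved), canon, tolerance = 1e-6)
    refl <- base %*% rot %*% diag(c(-1, 1))
    expect_equal(canonical_orient(refl), canon, tolerance = 1e-6)
  }
  expect_warning(canonical_orient(matrix(1, 4, 2)), "degenerate")
})

test_that("neuroscale transform is consistent and deterministic", {
  fps <- rand_fps(25, len = 128, seed = 6)
  d <- pairwise_distance_matrix(fps)
  m1 <- suppressWarnings(neuroscale_fit(fps, d, candidate_counts = 6,
                                        seed = 2))
  m2 <- suppressWarnings(neuroscale_fit(fps, d, candidate_counts = 6,
                                        seed = 2))
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$n_rbf, 6L)
  e <- neuroscale_transform(m1, fps)
  expect_identical(e$coords, neuroscale_transform(m1, fps)$coords)
  # duplicates map together
  dup <- rbind(fps[1, ], fps[1, ])
  ed <- neuroscale_transform(m1, dup)
  expect_equal(ed$coords[1, ], ed$coords[2, ])
  expect_error(neuroscale_transform(m1, rand_fps(3, len = 64)),
               "does not match")
})

test_that("neuroscale training improves on a random-weight map", {
  fps <- rand_fps(20, len = 128, seed = 8)
  d <- pairwise_distance_matrix(fps)
  m <- suppressWarnings(neuroscale_fit(fps, d, candidate_counts = 5,
                                       seed = 3))
  set.seed(1)
  rand_w <- m
  rand_w$weights <- matrix(rnorm(length(m$weights)), ncol = 2)
  e_rand <- neuroscale_transform(rand_w, fps)
  expect_lte(m$stress, stress(e_rand$coords, d))
})

test_that("neuroscale CV picks a sufficient center count on clustered data", {
  # 8 well-separated clusters need ~8 centers; 2 centers underfit
  set.seed(11)
  protos <- matrix(rbinom(8 * 256, 1, 0.25), nrow = 8)
  fps <- protos[rep(1:8, each = 5), ]
  flip <- matrix(rbinom(length(fps), 1, 0.01), nrow = nrow(fps))
  fps <- (fps + flip) %% 2L
  fps[rowSums(fps) == 0, 1] <- 1L
  d <- pairwise_distance_matrix(fps)
  m <- suppressWarnings(neuroscale_fit(fps, d, candidate_counts = c(2, 10),
                                       seed = 4))
  expect_equal(m$n_rbf, 10L)
  expect_lt(m$cv[["10"]], m$cv[["2"]])
  # held-out compound near a training cluster lands nearest that cluster
  probe <- protos[3, ]
  y <- neuroscale_transform(m, rbind(probe))$coords
  train_y <- neuroscale_transform(m, fps)$coords
  centroids <- apply(train_y, 2, function(col) tapply(col, rep(1:8, each = 5),
                                                      mean))
  dists <- sqrt(rowSums(sweep(centroids, 2, as.numeric(y))^2))
  expect_equal(unname(which.min(dists)), 3L)
})

test_that("small sets are rejected for sevenfold cross-validation", {
  fps <- rand_fps(10, seed = 9)
  expect_error(
    neuroscale_fit(fps, candidate_counts = c(2, 4), seed = 1),
    "too small"
  )
})
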