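test_that("tanimoto matches the set-overlap formula on constructed pairs", {
  a <- fp_bits(1:10, 32)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(fp_bits(1:4, 32), fp_bits(5:8, 32)), 0.0)
  # |A| = 4, |B| = 3, |A n B| = 2 -> 2 / (4 + 3 - 2)
  expect_equal(tanimoto(fp_bits(1:4, 32), fp_bits(c(1, 2, 9), 32)), 0.4)
  expect_equal(tanimoto_distance(a, a), 0.0)
  expect_equal(tanimoto_distance(fp_bits(1:4, 32), fp_bits(5:8, 32)), 1.0)
  expect_equal(tanimoto_distance(fp_bits(1:4, 32), fp_bits(c(1, 2, 9), 32)),
               0.6)
})

test_that("tanimoto rejects invalid input", {
  expect_error(tanimoto(fp_bits(1, 8), fp_bits(1, 16)), "length mismatch")
  expect_error(tanimoto(integer(8), integer(8)), "all-zero")
})

test_that("tanimoto is symmetric, bounded, and 1 iff identical", {
  set.seed(42)
  for (i in 1:25) {
    a <- rbinom(48, 1, runif(1, 0.1, 0.6))
    b <- rbinom(48, 1, runif(1, 0.1, 0.6))
    if (sum(a) == 0) a[1] <- 1L
    if (sum(b) == 0) b[1] <- 1L
    tc <- tanimoto(a, b)
    expect_equal(tc, tanimoto(b, a))
    expect_gte(tc, 0)
    expect_lte(tc, 1)
    expect_equal(tc == 1, identical(as.integer(a), as.integer(b)))
  }
})

test_that("pairwise distance matrix equals the per-pair brute force", {
  fps <- rbind(fp_bits(1:5, 16), fp_bits(3:9, 16), fp_bits(c(1, 9, 12), 16))
  d <- pairwise_distance_matrix(fps)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) {
        expect_equal(d[i, j], tanimoto_distance(fps[i, ], fps[j, ]))
      }
    }
  }
  one <- pairwise_distance_matrix(fps[1, , drop = FALSE])
  expect_equal(one, matrix(0, 1, 1, dimnames = list(NULL, NULL)),
               ignore_attr = TRUE)
})

test_that("similarity filter removes exactly the singletons and is idempotent", {
  # 3 mutually similar compounds + 2 singletons with disjoint bits
  fps <- rbind(fp_bits(1:10, 64), fp_bits(2:11, 64), fp_bits(c(1:9, 12), 64),
               fp_bits(30:33, 64), fp_bits(40:45, 64))
  cls <- activity_class("f", paste0("c", 1:5), fps, potency = 5:9)
  kept <- similarity_filter(cls, 0.4)
  expect_setequal(kept$ids, c("c1", "c2", "c3"))
  again <- similarity_filter(kept, 0.4)
  expect_identical(again$ids, kept$ids)

  # all compounds have a neighbor -> unchanged
  close_set <- activity_class("g", paste0("c", 1:3), fps[1:3, ], 5:7)
  expect_identical(similarity_filter(close_set, 0.4)$ids, close_set$ids)
  expect_warning(similarity_filter(
    activity_class("h", c("a", "b"), rbind(fp_bits(1:4, 64),
                                           fp_bits(10:14, 64)), 5:6), 0.4
  ), "removed all")
})

test_that("smooth reference selects the closed interquartile interval", {
  cls <- toy_class(1:8)
  sm <- smooth_reference(cls)
  # type-7 quartiles of 1..8 are 2.75 and 6.25
  expect_equal(sort(sm$potency), 3:6)
  expect_identical(sm$variant, "smooth")
  s <- potency_summary(cls)
  expect_equal(s$q1, unname(quantile(1:8, 0.25)))
  expect_true(all(sm$potency >= s$q1 & sm$potency <= s$q3))
  # complement union gives back the input
  expect_setequal(c(sm$ids, setdiff(cls$ids, sm$ids)), cls$ids)

  # degenerate: equal potencies keep everything
  eq <- toy_class(rep(5, 6))
  expect_equal(length(smooth_reference(eq)), 6L)
})

test_that("rugged reference keeps alternating septiles and the range", {
  cls <- toy_class(1:7)
  rg <- rugged_reference(cls)
  expect_equal(sort(rg$potency), c(1, 3, 5, 7))
  expect_identical(rg$variant, "rugged")
  expect_error(rugged_reference(toy_class(1:6)), "at least 7")

  set.seed(9)
  for (n in c(14, 23, 50, 100)) {
    pot <- sample(seq(4, 10, length.out = n))
    cls_n <- toy_class(pot, seed = n)
    rg_n <- rugged_reference(cls_n)
    expect_gte(length(rg_n), floor(4 * n / 7))
    expect_lte(length(rg_n), ceiling(4 * n / 7))
    expect_equal(min(rg_n$potency), min(pot))
    expect_equal(max(rg_n$potency), max(pot))
  }
  # exact 4/7 for divisible n
  cls700 <- toy_class(seq_len(700), seed = 700)
  expect_equal(length(rugged_reference(cls700)), 400L)
})

test_that("compound tables round-trip through bitstring and hex", {
  cls <- toy_class(c(5.2, 6.1, 7.9), len = 32)
  for (fmt in c("bitstring", "hex")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_compound_table(cls, path, format = fmt)
    back <- read_compound_table(path, name = "toy")
    expect_equal(back$ids, cls$ids)
    expect_equal(back$fps, cls$fps)
    expect_equal(back$potency, cls$potency)
  }
  # hex convention: first fingerprint bit is the MSB of the first digit
  expect_identical(fp_to_hex(c(1, 1, 1, 1, 0, 0, 0, 0)), "f0")
  expect_identical(fp_from_hex("80"), c(1L, rep(0L, 7)))
})

test_that("compound table validation names offending rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,potency,fingerprint",
               "a,5.0,0101", "b,NA,0110", "c,6.2,0011"), path)
  expect_error(read_compound_table(path), "row\\(s\\): 2")
  writeLines(c("id,potency", "a,5.0"), path)
  expect_error(read_compound_table(path), "fingerprint")
  writeLines(c("id,potency,fingerprint",
               "a,5.0,0101", "b,6.0,011011"), path)
  expect_error(read_compound_table(path), "inconsistent fingerprint lengths")
})

test_that("circular fingerprints are deterministic and ECFP-like", {
  fp1 <- circular_fingerprint("CCO", nbits = 256)
  fp2 <- circular_fingerprint("CCO", nbits = 256)
  expect_identical(fp1, fp2)
  expect_gte(sum(fp1), 1)
  # similar molecules overlap more than dissimilar ones
  t_close <- tanimoto(circular_fingerprint("CCCCO", nbits = 256),
                      circular_fingerprint("CCCCCO", nbits = 256))
  t_far <- tanimoto(circular_fingerprint("CCCCO", nbits = 256),
                    circular_fingerprint("c1ccccc1N(=O)=O", nbits = 256))
  expect_gt(t_close, t_far)
})
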