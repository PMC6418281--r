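test_that("the feature manifest is the fixed 730-name inventory", {
  m <- feature_manifest()
  expect_equal(nrow(m), 730L)
  expect_equal(anyDuplicated(m$name), 0L)
  expect_equal(unname(table(m$channel)[c("original", "LL", "LH", "HL", "HH")]),
               rep(146L, 5), ignore_attr = TRUE)
  counts <- table(m$family) / 5
  expect_equal(unname(counts["firstorder"]), 14, ignore_attr = TRUE)
  expect_equal(unname(counts["glcm"]), 88, ignore_attr = TRUE)
  expect_equal(unname(counts["glrlm"]), 44, ignore_attr = TRUE)

  shipped <- jsonlite::read_json(
    system.file("extdata", "feature_manifest.json", package = "radsig"),
    simplifyVector = TRUE
  )
  expect_equal(shipped$names, m$name)
})

test_that("first-order statistics match hand computations", {
  const <- first_order_features(make_roi(matrix(5, 4, 4)))
  expect_equal(unname(const[c("mean", "variance", "range", "uniformity",
                              "entropy")]),
               c(5, 0, 0, 1, 0))
  expect_equal(unname(const["skewness"]), 0)

  v <- make_roi(matrix(c(1, 2, 3, 4), 2, 2))
  fo <- first_order_features(v)
  expect_equal(unname(fo["mean"]), 2.5)
  expect_equal(unname(fo["variance"]), 1.25)          # population variance
  expect_equal(unname(fo["energy"]), 30)
  expect_equal(unname(fo["rms"]), sqrt(30 / 4))
  expect_equal(unname(fo["mad"]), 1)
  expect_equal(unname(fo["skewness"]), 0, tolerance = 1e-12)

  # two-pass reference for mean/variance on a random ROI
  set.seed(3)
  x <- matrix(runif(100, 0, 255), 10, 10)
  f2 <- first_order_features(make_roi(x))
  expect_equal(unname(f2["mean"]), sum(x) / 100, tolerance = 1e-10)
  expect_equal(unname(f2["variance"]), sum((x - mean(x))^2) / 100,
               tolerance = 1e-10)
})

test_that("GLCM matrices follow the symmetric pair-counting geometry", {
  q_const <- make_quantized(matrix(1L, 4, 4), Ng = 4)
  m <- glcm_matrix(q_const, "d0")
  expect_equal(m[1, 1], 1)
  expect_equal(sum(m), 1)

  q <- make_quantized(matrix(c(1L, 1L, 2L, 2L), 2, 2), Ng = 2)
  m90 <- glcm_matrix(q, "d90")
  expect_equal(m90[1, 1], 0.5)
  expect_equal(m90[2, 2], 0.5)
  expect_equal(m90[1, 2], 0)

  # direction with no pairs: single-row ROI has no vertical neighbors
  mask1 <- matrix(FALSE, 3, 5); mask1[2, ] <- TRUE
  qrow <- make_quantized(matrix(1L, 3, 5), Ng = 2, mask = mask1)
  expect_error(glcm_matrix(qrow, "d90"), "no valid co-occurrence pairs")
})

test_that("GLCM agrees with the brute-force pair oracle on random grids", {
  set.seed(11)
  for (k in 1:10) {
    g <- random_masked_grid(sample(6:12, 1), sample(6:12, 1), Ng = 6)
    q <- make_quantized(g$levels, Ng = 6, mask = g$mask)
    for (d in c("d0", "d45", "d90", "d135")) {
      counts <- oracle_glcm_counts(g$levels, g$mask, d, 6)
      if (sum(counts) == 0) next
      expect_equal(unclass(glcm_matrix(q, d)), counts / sum(counts),
                   ignore_attr = TRUE)
    }
  }
})

test_that("GLCM features evaluate Haralick formulas correctly", {
  single <- matrix(0, 3, 3); single[1, 1] <- 1
  f <- glcm_features(single)
  expect_equal(unname(f[c("energy", "entropy", "contrast",
                          "maximum_probability", "correlation")]),
               c(1, 0, 0, 1, 0))

  diag2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f2 <- glcm_features(diag2)
  expect_equal(unname(f2["contrast"]), 0)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["entropy"]), 1)            # 1 bit
  expect_equal(unname(f2["correlation"]), 1)        # perfectly aligned levels
  expect_equal(unname(f2["sum_average"]), 3)        # (2+4)/2
  expect_equal(unname(f2["dissimilarity"]), 0)

  set.seed(5)
  for (k in 1:10) {
    raw <- matrix(rexp(16), 4, 4)
    m <- (raw + t(raw)); m <- m / sum(m)
    fk <- glcm_features(m)
    expect_gte(fk[["contrast"]], 0)
    expect_gt(fk[["energy"]], 0)
    expect_lte(fk[["energy"]], 1)
    expect_gte(fk[["entropy"]], 0)
    expect_true(all(is.finite(fk)))
  }
})

test_that("GLRLM counts maximal runs and conserves pixels", {
  q_const <- make_quantized(matrix(1L, 4, 4), Ng = 2)
  m <- glrlm_matrix(q_const, "d0")
  expect_equal(m[1, 4], 4)           # 4 rows, each one run of length 4
  expect_equal(sum(m), 4)

  row <- make_quantized(matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5), Ng = 2)
  m2 <- glrlm_matrix(row, "d0")
  expect_equal(m2[1, 2], 1)
  expect_equal(m2[2, 3], 1)
  expect_equal(sum(m2), 2)

  set.seed(13)
  for (k in 1:10) {
    g <- random_masked_grid(sample(6:12, 1), sample(6:12, 1), Ng = 4)
    q <- make_quantized(g$levels, Ng = 4, mask = g$mask)
    for (d in c("d0", "d45", "d90", "d135")) {
      got <- glrlm_matrix(q, d)
      want <- oracle_glrlm_counts(g$levels, g$mask, d, 4, ncol(got))
      expect_equal(unclass(got), want, ignore_attr = TRUE)
      # conservation: every ROI cell in exactly one maximal run
      expect_equal(sum(got %*% seq_len(ncol(got))), sum(g$mask))
    }
  }
})

test_that("GLRLM features evaluate run-length formulas correctly", {
  m <- matrix(0, 2, 4); m[1, 4] <- 1
  f <- glrlm_features(m, n_pixels = 4)
  expect_equal(unname(f[c("sre", "lre", "rp")]), c(1 / 16, 16, 0.25))

  m1 <- matrix(0, 3, 3); m1[, 1] <- c(2, 3, 1)   # all runs length 1
  f1 <- glrlm_features(m1, n_pixels = 6)
  expect_equal(unname(f1["sre"]), 1)
  expect_equal(unname(f1["lre"]), 1)
  expect_equal(unname(f1["rp"]), 1)
  expect_error(glrlm_features(matrix(0, 2, 2), n_pixels = 4), "empty")
})

test_that("extract_all yields 730 finite, deterministic, ordered features", {
  im <- generate_tumor_image(0.3, seed = 99)
  roi <- apply_mask(im$image, im$mask)
  fv <- extract_all(roi)
  expect_length(fv, 730L)
  expect_identical(names(fv), feature_manifest()$name)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(roi))

  const <- make_roi(matrix(100, 16, 16))
  fc <- extract_all(const)
  expect_length(fc, 730L)
  expect_true(all(is.finite(fc)))
  ent <- grepl("entropy", names(fc))
  var <- grepl("variance", names(fc))
  expect_true(all(fc[ent] == 0))
  expect_true(all(fc[var] == 0))
})

test_that("features are invariant under block-aligned ROI translation", {
  set.seed(21)
  patch <- matrix(runif(12 * 12, 0, 255), 12, 12)
  pmask <- matrix(runif(144) < 0.9, 12, 12)
  embed <- function(dr, dc) {
    px <- matrix(0, 24, 24); mk <- matrix(FALSE, 24, 24)
    px[dr + 1:12, dc + 1:12] <- patch
    mk[dr + 1:12, dc + 1:12] <- pmask
    make_roi(px, mk)
  }
  f1 <- extract_all(embed(2, 2))
  f2 <- extract_all(embed(8, 6))   # even shifts keep 2x2 block alignment
  expect_equal(f1, f2, tolerance = 1e-12)
})
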