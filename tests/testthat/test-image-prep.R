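test_that("grayscale conversion uses BT.601 luminance and is idempotent", {
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(255, 255, 255)
  rgb[1, 2, ] <- c(0, 0, 0)
  rgb[2, 1, ] <- c(100, 150, 200)
  rgb[2, 2, ] <- c(10, 20, 30)
  g <- to_grayscale(pixel_grid(rgb))
  expect_equal(g$channels, 1L)
  expect_equal(g$values[1, 1], 255)
  expect_equal(g$values[1, 2], 0)
  expect_equal(g$values[2, 1], 141)  # round(0.299*100 + 0.587*150 + 0.114*200)
  expect_identical(to_grayscale(g), g)
})

test_that("PNG images round-trip losslessly through load_image", {
  img <- matrix(sample(0:255, 64 * 48, replace = TRUE), 48, 64)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img / 255, path)
  loaded <- load_image(path)
  expect_equal(loaded$channels, 1L)
  expect_equal(loaded$width, 64L)
  expect_equal(loaded$height, 48L)
  expect_equal(loaded$values, img)
})

test_that("RGB JPEG loads with 3 channels and converts", {
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".jpg")
  jpeg::writeJPEG(rgb, path)
  loaded <- load_image(path)
  expect_equal(loaded$channels, 3L)
  expect_equal(to_grayscale(loaded)$channels, 1L)
  expect_error(load_image(file.path(tempdir(), "nope.png")), "does not exist")
})

test_that("apply_mask counts ROI cells and rejects degenerate masks", {
  g <- matrix(0, 10, 10)
  expect_equal(apply_mask(g, matrix(TRUE, 10, 10))$n_roi, 100L)

  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 == 0)
  expect_equal(apply_mask(matrix(0, 8, 8), cb)$n_roi, 32L)

  m15 <- matrix(FALSE, 10, 10)
  m15[1:15] <- TRUE
  expect_error(apply_mask(g, m15), "degenerate ROI")
  expect_error(apply_mask(g, matrix(TRUE, 9, 9)), "dimensions")
})

test_that("polygon masks fill with the even-odd rule", {
  # square with corners (2,2)-(6,6) in 0-based coords on a 10x10 image
  path <- withr::local_tempfile(fileext = ".roi.txt")
  writeLines(c("2,2", "6,2", "6,6", "2,6"), path)
  mask <- read_mask(path, width = 10, height = 10)
  expect_equal(dim(mask), c(10L, 10L))
  expect_true(mask[4, 4])    # center of the square (1-based row/col 3..7)
  expect_false(mask[1, 1])
  expect_false(mask[9, 9])
  expect_equal(sum(mask), 16)  # interior pixel centers strictly inside
})

test_that("normalize_roi rescales ROI to [0, 255] and is idempotent", {
  roi <- make_roi(matrix(c(10, 20, 30, 10, 30, 20, 20, 10, 30), 3, 3))
  norm <- normalize_roi(roi)
  expect_equal(sort(unique(as.vector(norm$pixels))), c(0, 127.5, 255))

  const <- normalize_roi(make_roi(matrix(7, 4, 4)))
  expect_true(all(const$pixels == 0))

  full <- make_roi(matrix(c(0, 255, rep(128, 14)), 4, 4))
  expect_equal(normalize_roi(full)$pixels, full$pixels)
  expect_equal(normalize_roi(norm)$pixels, norm$pixels, tolerance = 1e-9)
})

test_that("quantize bins ROI values into 1..Ng with max attaining Ng", {
  expect_true(all(quantize(make_roi(matrix(5, 4, 4)), 32)$levels == 1L))

  q2 <- quantize(make_roi(matrix(c(0, 255), 2, 2)), 2)
  expect_equal(sort(unique(as.vector(q2$levels))), c(1L, 2L))

  q4 <- quantize(make_roi(matrix(c(0, 100, 200, 255), 2, 2)), 4)
  expect_equal(as.vector(q4$levels), c(1L, 2L, 4L, 4L))

  expect_error(quantize(make_roi(matrix(1:16, 4, 4)), 1), "Ng")
})

test_that("quantization is invariant under increasing affine rescaling", {
  set.seed(42)
  for (k in 1:20) {
    v <- matrix(runif(64, 0, 255), 8, 8)
    a <- runif(1, 0.1, 5)
    b <- runif(1, -50, 50)
    q1 <- quantize(make_roi(v), 16)
    q2 <- quantize(make_roi(a * v + b), 16)
    expect_identical(q1$levels, q2$levels)
  }
})

test_that("Haar decomposition of a constant image puts all energy in LL", {
  roi <- make_roi(matrix(3, 8, 8))
  bands <- wavelet_decompose(roi)
  expect_equal(names(bands), c("LL", "HL", "LH", "HH"))
  expect_true(all(bands$LL$pixels == 6))   # orthonormal: (c+c+c+c)/2 = 2c
  expect_true(all(bands$LH$pixels == 0))
  expect_true(all(bands$HL$pixels == 0))
  expect_true(all(bands$HH$pixels == 0))
  expect_equal(dim(bands$LL$pixels), c(4L, 4L))
})

test_that("Haar analysis/synthesis is a perfect-reconstruction pair", {
  set.seed(1)
  x <- matrix(runif(16 * 16, 0, 255), 16, 16)
  bands <- wavelet_decompose(make_roi(x))
  rec <- wavelet_reconstruct(lapply(bands, `[[`, "pixels"), 16, 16)
  expect_lt(max(abs(rec - x)), 1e-9)

  # odd dimensions: subband size is the ceiling of half
  y <- matrix(runif(9 * 13, 0, 255), 9, 13)
  b2 <- wavelet_decompose(make_roi(y, matrix(TRUE, 9, 13)))
  expect_equal(dim(b2$LL$pixels), c(5L, 7L))
  rec2 <- wavelet_reconstruct(lapply(b2, `[[`, "pixels"), 9, 13)
  expect_lt(max(abs(rec2 - y)), 1e-9)
  expect_error(wavelet_decompose(make_roi(matrix(1:9, 3, 3))), "4x4")
})

test_that("subband masks follow the all-parents rule with any-parent fallback", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:10, 3:10] <- TRUE          # 64 cells, aligned to 2x2 blocks
  roi <- make_roi(matrix(runif(144), 12, 12), mask)
  bands <- wavelet_decompose(roi)
  expect_equal(attr(bands$LL, "mask_rule"), "all")
  expect_equal(bands$LL$n_roi, 16L)  # 8x8 parent block -> 4x4 subband
  expect_lte(bands$LL$n_roi, ceiling(sum(mask) / 4))

  # sparse mask: all-parents leaves < 16 cells, triggering the fallback
  sparse <- matrix(FALSE, 12, 12)
  sparse[cbind(seq(1, 12), c(1:6, 1:6) * 2)] <- TRUE
  sparse[5:8, 5:8] <- TRUE
  roi2 <- make_roi(matrix(runif(144), 12, 12), sparse)
  bands2 <- wavelet_decompose(roi2)
  expect_equal(attr(bands2$LL, "mask_rule"), "any")
  expect_gte(bands2$LL$n_roi, 4L)
})
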