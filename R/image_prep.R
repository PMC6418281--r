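#' Load a PNG or JPEG image as a pixel grid
#'
#' Reads an 8-bit image into an integer pixel grid with values in 0-255.
#' Alpha channels are dropped; single-channel images come back as matrices,
#' RGB images as height x width x 3 arrays. Coordinates are row-major with
#' the origin at the top-left corner.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A `pixel_grid` object: list with `values` (matrix or 3D array on
#'   the 0-255 scale), `width`, `height` and `channels` (1 or 3).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop("unsupported image format '", ext, "': ", path)
    ),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) {
      raw <- raw[, , 1:3, drop = FALSE]   # drop alpha
    } else {
      raw <- raw[, , 1L]                  # gray + alpha
    }
  }
  values <- round(raw * 255)
  pixel_grid(values)
}

#' Construct a pixel grid from raw values
#'
#' @param values Matrix (grayscale) or height x width x 3 array (RGB) with
#'   intensities in \[0, 255\].
#' @return A `pixel_grid` object.
#' @export
pixel_grid <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) < 2L) stop("values must be a matrix or 3D array")
  channels <- if (length(d) == 3L) d[3] else 1L
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3, got ", channels)
  if (d[1] < 2L || d[2] < 2L) stop("image must be at least 2x2, got ",
                                   d[1], "x", d[2])
  if (anyNA(values) || min(values) < 0 || max(values) > 255) {
    stop("pixel values must be finite and in [0, 255]")
  }
  if (channels == 1L && length(d) == 3L) values <- values[, , 1L]
  structure(
    list(values = values, width = d[2], height = d[1], channels = channels),
    class = "pixel_grid"
  )
}

#' Convert a pixel grid to grayscale luminance
#'
#' RGB images are converted with the ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer; hue and
#' saturation are discarded. Single-channel grids pass through unchanged.
#'
#' @param grid A `pixel_grid`.
#' @return A single-channel `pixel_grid`.
#' @export
to_grayscale <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (grid$channels == 1L) return(grid)
  v <- grid$values
  lum <- round(0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3])
  pixel_grid(lum)
}

#' Read an ROI mask from PNG or polygon text
#'
#' PNG masks are interpreted as nonzero = inside ROI. Polygon masks
#' (`*.roi.txt`) list one `x,y` vertex per line in 0-based pixel
#' coordinates; the polygon is filled with the even-odd rule over pixel
#' centers, which requires the target image dimensions.
#'
#' @param path Mask file path.
#' @param width,height Image dimensions in pixels; required for polygon
#'   masks, checked against PNG masks when supplied.
#' @return Logical matrix, `TRUE` inside the ROI.
#' @export
read_mask <- function(path, width = NULL, height = NULL) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    mask <- raw > 0
    if (!is.null(height) && !identical(dim(mask), c(height, width))) {
      stop("mask dimensions ", nrow(mask), "x", ncol(mask),
           " do not match image ", height, "x", width, ": ", path)
    }
    return(mask)
  }
  if (is.null(width) || is.null(height)) {
    stop("polygon masks need the target image width and height")
  }
  verts <- read.csv(path, header = FALSE, col.names = c("x", "y"))
  if (nrow(verts) < 3L) stop("polygon mask needs at least 3 vertices: ", path)
  polygon_mask(verts$x, verts$y, width, height)
}

# Even-odd polygon fill over pixel centers. Vertices are 0-based pixel
# coordinates; pixel (row r, col c) has center (c, r).
polygon_mask <- function(vx, vy, width, height) {
  n <- length(vx)
  px <- rep(seq_len(width) - 1L, each = height)
  py <- rep(seq_len(height) - 1L, times = width)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Attach an ROI mask to a grayscale image
#'
#' @param grid Single-channel `pixel_grid` or a numeric matrix.
#' @param mask Logical matrix of the same dimensions; at least 16 cells must
#'   be `TRUE`.
#' @return An `roi_image`: list with `pixels` (numeric matrix), `mask` and
#'   `n_roi`.
#' @export
apply_mask <- function(grid, mask) {
  pixels <- if (inherits(grid, "pixel_grid")) {
    if (grid$channels != 1L) stop("apply_mask needs a single-channel image")
    grid$values
  } else {
    as.matrix(grid)
  }
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(pixels), dim(mask))) {
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match image ", paste(dim(pixels), collapse = "x"))
  }
  n_roi <- sum(mask)
  if (n_roi < 16L) {
    stop("degenerate ROI: only ", n_roi, " mask cells (need >= 16)")
  }
  structure(list(pixels = pixels, mask = mask, n_roi = n_roi),
            class = "roi_image")
}

#' Min-max normalize an ROI image
#'
#' Linearly rescales intensities so that the minimum over ROI cells maps to 0
#' and the maximum to 255, giving every patient's ROI a common intensity
#' range. The affine map is applied to the whole grid (so subsequent wavelet
#' filtering sees a consistent surface), but only ROI cells define it. A
#' constant ROI maps the whole grid to 0.
#'
#' @param roi An `roi_image`.
#' @return The normalized `roi_image`; idempotent.
#' @export
normalize_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi$pixels[roi$mask]
  lo <- min(v)
  hi <- max(v)
  roi$pixels <- if (hi == lo) {
    array(0, dim(roi$pixels))
  } else {
    (roi$pixels - lo) * (255 / (hi - lo))
  }
  roi
}

#' Quantize ROI intensities to Ng gray levels
#'
#' ROI cell with value `v` receives level
#' `min(Ng, floor((v - min) / (max - min) * Ng) + 1)`, so levels span 1..Ng
#' and only the ROI maximum attains level Ng. A constant ROI maps to level 1
#' everywhere. Quantization is invariant under strictly increasing affine
#' rescaling of the intensities.
#'
#' @param roi An `roi_image`.
#' @param Ng Number of gray levels (>= 2); default 32.
#' @return A `quantized_roi`: list with integer `levels` (0 outside the
#'   mask), `Ng` and `mask`.
#' @export
quantize <- function(roi, Ng = 32L) {
  stopifnot(inherits(roi, "roi_image"))
  Ng <- as.integer(Ng)
  if (is.na(Ng) || Ng < 2L) stop("Ng must be an integer >= 2")
  v <- roi$pixels[roi$mask]
  lo <- min(v)
  hi <- max(v)
  levels <- matrix(0L, nrow(roi$pixels), ncol(roi$pixels))
  if (hi == lo) {
    levels[roi$mask] <- 1L
  } else {
    lv <- floor((v - lo) / (hi - lo) * Ng) + 1
    levels[roi$mask] <- as.integer(pmin(lv, Ng))
  }
  structure(list(levels = levels, Ng = Ng, mask = roi$mask),
            class = "quantized_roi")
}

# Pad a matrix to even dimensions by half-sample symmetric extension
# (duplicate the last row/column).
pad_even <- function(m) {
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  m
}

# Orthonormal single-level Haar analysis on non-overlapping 2x2 blocks.
# Band labels: first letter = filter along x (columns), second = along y
# (rows); e.g. HL is high-pass in x, low-pass in y.
haar_analysis <- function(m) {
  m <- pad_even(m)
  ro <- seq(1L, nrow(m), by = 2L)
  co <- seq(1L, ncol(m), by = 2L)
  a <- m[ro, co, drop = FALSE]
  b <- m[ro, co + 1L, drop = FALSE]
  cc <- m[ro + 1L, co, drop = FALSE]
  d <- m[ro + 1L, co + 1L, drop = FALSE]
  list(
    LL = (a + b + cc + d) / 2,
    HL = (a - b + cc - d) / 2,
    LH = (a + b - cc - d) / 2,
    HH = (a - b - cc + d) / 2
  )
}

#' Reconstruct an image from single-level Haar subbands
#'
#' Inverse of the analysis performed by [wavelet_decompose()]; exact up to
#' floating-point rounding. Used to verify the perfect-reconstruction
#' property of the transform.
#'
#' @param bands List with numeric matrices `LL`, `HL`, `LH`, `HH` of equal
#'   dimensions.
#' @param height,width Dimensions of the original image (the transform pads
#'   odd sizes; reconstruction crops back).
#' @return Numeric matrix `height` x `width`.
#' @export
wavelet_reconstruct <- function(bands, height, width) {
  LL <- bands$LL; HL <- bands$HL; LH <- bands$LH; HH <- bands$HH
  nr <- 2L * nrow(LL)
  nc <- 2L * ncol(LL)
  out <- matrix(0, nr, nc)
  ro <- seq(1L, nr, by = 2L)
  co <- seq(1L, nc, by = 2L)
  out[ro, co] <- (LL + HL + LH + HH) / 2
  out[ro, co + 1L] <- (LL - HL + LH - HH) / 2
  out[ro + 1L, co] <- (LL + HL - LH - HH) / 2
  out[ro + 1L, co + 1L] <- (LL - HL - LH + HH) / 2
  out[seq_len(height), seq_len(width), drop = FALSE]
}

#' Single-level 2D Haar decomposition of an ROI image
#'
#' Computes the four orthonormal Haar subbands (LL, LH, HL, HH) at half
#' resolution (ceiling division; odd dimensions are extended symmetrically
#' first). The ROI mask is propagated to each subband: a subband cell is
#' inside the ROI iff all four parent pixels are ("all-parents" rule, which
#' avoids contaminating subband statistics with out-of-ROI pixels); if fewer
#' than `min_cells` cells survive, the rule falls back to "any parent".
#'
#' @param roi An `roi_image` with both dimensions >= 4.
#' @param min_cells Minimum subband ROI size before falling back to the
#'   any-parent mask rule (default 16).
#' @return Named list of four `roi_image` objects (`LL`, `LH`, `HL`, `HH`),
#'   each carrying a `mask_rule` attribute (`"all"` or `"any"`).
#' @export
wavelet_decompose <- function(roi, min_cells = 16L) {
  stopifnot(inherits(roi, "roi_image"))
  if (nrow(roi$pixels) < 4L || ncol(roi$pixels) < 4L) {
    stop("image must be at least 4x4 for wavelet decomposition")
  }
  bands <- haar_analysis(roi$pixels)
  mp <- pad_even(roi$mask * 1)
  ro <- seq(1L, nrow(mp), by = 2L)
  co <- seq(1L, ncol(mp), by = 2L)
  parents <- mp[ro, co] + mp[ro, co + 1L] + mp[ro + 1L, co] + mp[ro + 1L, co + 1L]
  mask_all <- parents == 4
  mask_any <- parents > 0
  use_any <- sum(mask_all) < min_cells
  mask <- if (use_any) mask_any else mask_all
  rule <- if (use_any) "any" else "all"
  lapply(bands, function(b) {
    structure(
      list(pixels = b, mask = mask, n_roi = sum(mask)),
      class = "roi_image", mask_rule = rule
    )
  })
}
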