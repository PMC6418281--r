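# Canonical feature inventory ------------------------------------------------

.radsig_channels <- c("original", "LL", "LH", "HL", "HH")
.radsig_directions <- c("d0", "d45", "d90", "d135")

# (row, col) offsets per direction; 0 deg = horizontal neighbor to the right.
.radsig_offsets <- list(
  d0 = c(0L, 1L), d45 = c(-1L, 1L), d90 = c(-1L, 0L), d135 = c(-1L, -1L)
)

.radsig_firstorder <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "maximum",
  "range", "iqr", "energy", "entropy", "uniformity", "rms", "mad"
)

.radsig_glcm <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "cluster_tendency", "dissimilarity", "energy", "entropy",
  "homogeneity", "inverse_difference", "idn", "idmn", "maximum_probability",
  "sum_squares_variance", "sum_average", "sum_variance", "sum_entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2"
)

.radsig_glrlm <- c(
  "sre", "lre", "gln", "rln", "rp",
  "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"
)

#' The canonical 730-feature manifest
#'
#' The inventory is fixed: for each of the 5 channels (original image plus
#' the LL/LH/HL/HH Haar subbands) there are 14 first-order statistics, 22
#' co-occurrence (GLCM) features in each of 4 directions and 11 run-length
#' (GLRLM) features in each of 4 directions — 146 per channel, 730 in total.
#' Names follow `channel__family__feature[__direction]` and their order here
#' is the canonical column order of every feature table the package writes.
#'
#' @return Data frame with columns `name`, `channel`, `family`, `feature`,
#'   `direction` (`NA` for first-order rows); 730 rows.
#' @export
feature_manifest <- function() {
  cached <- .radsig_cache$manifest
  if (!is.null(cached)) return(cached)
  m <- build_feature_manifest()
  .radsig_cache$manifest <- m
  m
}

.radsig_cache <- new.env(parent = emptyenv())

build_feature_manifest <- function() {
  rows <- list()
  for (ch in .radsig_channels) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste(ch, "firstorder", .radsig_firstorder, sep = "__"),
      channel = ch, family = "firstorder", feature = .radsig_firstorder,
      direction = NA_character_
    )
    for (feat in .radsig_glcm) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(ch, "glcm", feat, .radsig_directions, sep = "__"),
        channel = ch, family = "glcm", feature = feat,
        direction = .radsig_directions
      )
    }
    for (feat in .radsig_glrlm) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(ch, "glrlm", feat, .radsig_directions, sep = "__"),
        channel = ch, family = "glrlm", feature = feat,
        direction = .radsig_directions
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the feature manifest as versioned JSON
#'
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_manifest <- function(path) {
  m <- feature_manifest()
  jsonlite::write_json(
    list(manifest_version = "1.0", n_features = nrow(m), names = m$name),
    path, auto_unbox = TRUE, pretty = FALSE
  )
  invisible(path)
}

# First-order statistics -------------------------------------------------------

#' First-order intensity statistics of an ROI
#'
#' Fourteen statistics of the ROI intensity distribution. Moments are
#' population moments; kurtosis is non-excess (a normal sample gives ~3);
#' skewness and kurtosis of a constant ROI are defined as 0. Entropy
#' (Shannon, base 2) and uniformity are computed on the `Ng`-bin histogram
#' of the quantized intensities.
#'
#' @param roi An `roi_image`.
#' @param Ng Histogram bin count for entropy/uniformity (default 32).
#' @return Named numeric vector of length 14.
#' @export
first_order_features <- function(roi, Ng = 32L) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi$pixels[roi$mask]
  n <- length(v)
  if (n < 4L) stop("degenerate ROI: ", n, " cells")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  lev <- quantize(roi, Ng)$levels[roi$mask]
  p <- tabulate(lev, nbins = Ng) / n
  p <- p[p > 0]
  c(
    mean = mu,
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    median = median(v),
    minimum = min(v),
    maximum = max(v),
    range = max(v) - min(v),
    iqr = q[2] - q[1],
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    rms = sqrt(mean(v^2)),
    mad = mean(abs(v - mu))
  )
}

# GLCM -------------------------------------------------------------------------

# Ng-dependent constant structures for glcm_features, cached per level count:
# index matrices, distance-weight matrices, and 0/1 aggregation matrices that
# map a vectorized GLCM onto its p_{x+y} / p_{x-y} diagonal bands.
glcm_consts <- function(ng) {
  key <- as.character(ng)
  cached <- .radsig_cache$glcm[[key]]
  if (!is.null(cached)) return(cached)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  d <- i - j
  out <- list(
    i = i, j = j, ij = i * j, d2 = d^2, absd = abs(d),
    w_idm = 1 / (1 + d^2), w_id = 1 / (1 + abs(d)),
    w_idn = 1 / (1 + abs(d) / ng), w_idmn = 1 / (1 + d^2 / ng^2),
    ksum = 2:(2 * ng), kdiff = 0:(ng - 1)
  )
  if (is.null(.radsig_cache$glcm)) .radsig_cache$glcm <- list()
  .radsig_cache$glcm[[key]] <- out
  out
}

#' Gray-level co-occurrence matrix
#'
#' Counts level pairs at unit distance in one of four directions, restricted
#' to pairs whose two cells are both inside the ROI. Counting is symmetric
#' (each pair enters in both orders) and the matrix is normalized to sum 1.
#'
#' @param q A `quantized_roi`.
#' @param direction One of `"d0"`, `"d45"`, `"d90"`, `"d135"`; offsets in
#'   (row, col) are (0,1), (-1,1), (-1,0), (-1,-1).
#' @return A `glcm_matrix`: Ng x Ng numeric matrix summing to 1, with
#'   attributes `direction` and `n_pairs` (number of ordered pairs counted).
#' @export
glcm_matrix <- function(q, direction = "d0") {
  stopifnot(inherits(q, "quantized_roi"))
  direction <- match.arg(direction, .radsig_directions)
  off <- .radsig_offsets[[direction]]
  counts <- glcm_count_cpp(q$levels, q$mask, off[1], off[2], q$Ng)
  total <- sum(counts)
  if (total == 0) {
    stop("no valid co-occurrence pairs in direction ", direction)
  }
  structure(counts / total, class = "glcm_matrix",
            direction = direction, n_pairs = total)
}

#' Haralick-family features of a GLCM
#'
#' The canonical 22-feature set computed from a normalized symmetric GLCM.
#' Logarithms are base 2 with the 0 log 0 = 0 convention; correlation and
#' the first information measure of correlation are defined as 0 when their
#' denominators vanish (constant ROI).
#'
#' @param m A normalized GLCM (matrix summing to 1).
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(m) {
  ng <- nrow(m)
  cc <- glcm_consts(ng)
  i <- cc$i
  j <- cc$j
  px <- rowSums(m)
  mu <- sum(seq_len(ng) * px)            # symmetric: mu_x = mu_y
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  sig <- sqrt(sig2)

  # diagonal-band distributions p_{x+y}, p_{x-y}
  ksum <- cc$ksum
  kdiff <- cc$kdiff
  bands <- glcm_band_sums_cpp(unclass(m))
  psum <- bands$psum
  pdiff <- bands$pdiff

  ent <- function(p) {          # -sum p log2 p with 0 log 0 = 0
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  sa <- sum(ksum * psum)
  da <- sum(kdiff * pdiff)

  hxy <- ent(m)
  hx <- ent(px)
  pxy <- outer(px, px)
  pos <- m > 0                  # m > 0 implies pxy > 0
  hxy1 <- -sum(m[pos] * log2(pxy[pos]))
  hxy2 <- ent(pxy)
  denom <- max(hx, hx)                    # HX = HY for symmetric matrices
  imc1 <- if (denom > 0) (hxy - hxy1) / denom else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))

  autoc <- sum(cc$ij * m)
  clus <- (i + j - 2 * mu)
  clus2 <- clus * clus
  c(
    autocorrelation = autoc,
    contrast = sum(cc$d2 * m),
    correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 0,
    cluster_prominence = sum(clus2 * clus2 * m),
    cluster_shade = sum(clus2 * clus * m),
    cluster_tendency = sum(clus2 * m),
    dissimilarity = sum(cc$absd * m),
    energy = sum(m^2),
    entropy = hxy,
    homogeneity = sum(m * cc$w_idm),
    inverse_difference = sum(m * cc$w_id),
    idn = sum(m * cc$w_idn),
    idmn = sum(m * cc$w_idmn),
    maximum_probability = max(m),
    sum_squares_variance = sum((i - mu)^2 * m),
    sum_average = sa,
    sum_variance = sum((ksum - sa)^2 * psum),
    sum_entropy = ent(psum),
    difference_variance = sum((kdiff - da)^2 * pdiff),
    difference_entropy = ent(pdiff),
    imc1 = imc1,
    imc2 = imc2
  )
}

# GLRLM ------------------------------------------------------------------------

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along a direction, restricted to
#' ROI cells; a mask gap terminates a run. Every ROI cell belongs to exactly
#' one maximal run, so `sum(j * entry[i, j]) = n_roi`.
#'
#' @inheritParams glcm_matrix
#' @return A `glrlm_matrix`: Ng x Lmax count matrix with attributes
#'   `direction` and `n_pixels`.
#' @export
glrlm_matrix <- function(q, direction = "d0") {
  stopifnot(inherits(q, "quantized_roi"))
  direction <- match.arg(direction, .radsig_directions)
  off <- .radsig_offsets[[direction]]
  maxlen <- max(dim(q$levels))
  counts <- glrlm_count_cpp(q$levels, q$mask, off[1], off[2], q$Ng, maxlen)
  used <- which(colSums(counts) > 0)
  if (length(used)) {
    counts <- counts[, seq_len(max(used)), drop = FALSE]
  }
  structure(counts, class = "glrlm_matrix",
            direction = direction, n_pixels = sum(q$mask))
}

#' Run-length features of a GLRLM
#'
#' The standard 11-feature run-length set (short/long-run emphasis,
#' gray-level and run-length non-uniformity, run percentage, and the
#' low/high gray-level variants). Run percentage is the run count divided by
#' the ROI pixel count.
#'
#' @param m A `glrlm_matrix` (or count matrix with attribute `n_pixels`).
#' @param n_pixels ROI cell count; taken from the matrix attribute when
#'   missing.
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(m, n_pixels = attr(m, "n_pixels")) {
  nr_tot <- sum(m)
  if (nr_tot == 0) stop("empty run-length matrix")
  ng <- nrow(m)
  lmax <- ncol(m)
  key <- paste0(ng, "x", lmax)
  cached <- .radsig_cache$glrlm[[key]]
  if (is.null(cached)) {
    cached <- list(
      i2 = matrix(seq_len(ng)^2, ng, lmax),
      j2 = matrix(rep(seq_len(lmax)^2, each = ng), ng, lmax)
    )
    if (is.null(.radsig_cache$glrlm)) .radsig_cache$glrlm <- list()
    .radsig_cache$glrlm[[key]] <- cached
  }
  i2 <- cached$i2
  j2 <- cached$j2
  c(
    sre = sum(m / j2) / nr_tot,
    lre = sum(m * j2) / nr_tot,
    gln = sum(rowSums(m)^2) / nr_tot,
    rln = sum(colSums(m)^2) / nr_tot,
    rp = nr_tot / n_pixels,
    lglre = sum(m / i2) / nr_tot,
    hglre = sum(m * i2) / nr_tot,
    srlgle = sum(m / (i2 * j2)) / nr_tot,
    srhgle = sum(m * i2 / j2) / nr_tot,
    lrlgle = sum(m * j2 / i2) / nr_tot,
    lrhgle = sum(m * i2 * j2) / nr_tot
  )
}

# Full extraction --------------------------------------------------------------

#' Default texture-extraction configuration
#'
#' @param Ng Gray-level count for quantization (default 32).
#' @return List of extraction settings.
#' @export
texture_config <- function(Ng = 32L) {
  list(Ng = as.integer(Ng), wavelet = "haar")
}

# 146 features for one channel (an roi_image, already normalized).
channel_features <- function(roi, Ng) {
  fo <- first_order_features(roi, Ng)
  q <- quantize(roi, Ng)
  glcm <- lapply(.radsig_directions, function(d) {
    tryCatch(glcm_features(glcm_matrix(q, d)),
             error = function(e) setNames(numeric(22), .radsig_glcm))
  })
  glrlm <- lapply(.radsig_directions, function(d) {
    glrlm_features(glrlm_matrix(q, d))
  })
  # manifest order: first-order, then per glcm feature x direction, then glrlm
  glcm_mat <- do.call(cbind, glcm)      # 22 x 4
  glrlm_mat <- do.call(cbind, glrlm)    # 11 x 4
  c(fo, as.numeric(t(glcm_mat)), as.numeric(t(glrlm_mat)))
}

#' Extract the full 730-feature vector from an ROI image
#'
#' Normalizes the ROI, computes its single-level Haar subbands, then for
#' each of the five channels (original, LL, LH, HL, HH — each min-max
#' normalized and quantized independently) computes 14 first-order, 88 GLCM
#' (22 features x 4 directions) and 44 GLRLM (11 x 4) features. Output
#' length and order always match [feature_manifest()].
#'
#' @param roi An `roi_image`.
#' @param config Extraction settings from [texture_config()].
#' @return Named numeric vector of length 730, all finite.
#' @export
# Crop an roi_image to the mask bounding box, keeping the top-left corner
# on an even (0-based) offset so 2x2 wavelet blocks stay aligned with the
# uncropped image; all features are unchanged (no pixel pair, run or block
# crosses the empty margin).
crop_roi <- function(roi) {
  rows <- range(which(rowSums(roi$mask) > 0))
  cols <- range(which(colSums(roi$mask) > 0))
  r0 <- rows[1] - (rows[1] - 1) %% 2    # snap to odd 1-based index
  c0 <- cols[1] - (cols[1] - 1) %% 2
  r1 <- max(rows[2], r0 + 3)            # keep at least 4x4 for the wavelet
  c1 <- max(cols[2], c0 + 3)
  if (r1 > nrow(roi$mask) || c1 > ncol(roi$mask)) return(roi)
  structure(list(pixels = roi$pixels[r0:r1, c0:c1, drop = FALSE],
                 mask = roi$mask[r0:r1, c0:c1, drop = FALSE],
                 n_roi = roi$n_roi),
            class = "roi_image")
}

extract_all <- function(roi, config = texture_config()) {
  stopifnot(inherits(roi, "roi_image"))
  norm <- normalize_roi(crop_roi(roi))
  bands <- wavelet_decompose(norm)
  channels <- list(
    original = norm,
    LL = normalize_roi(bands$LL),
    LH = normalize_roi(bands$LH),
    HL = normalize_roi(bands$HL),
    HH = normalize_roi(bands$HH)
  )
  out <- unlist(lapply(channels, channel_features, Ng = config$Ng),
                use.names = FALSE)
  names(out) <- feature_manifest()$name
  stopifnot(length(out) == 730L, all(is.finite(out)))
  out
}

#' Extract features for a whole cohort
#'
#' @param patients List of patients, each with elements `id` and `roi` (an
#'   `roi_image`), as produced by [generate_cohort()] or [read_cohort()].
#' @param config Extraction settings from [texture_config()].
#' @return Data frame: first column `id`, then the 730 manifest features.
#' @export
extract_cohort <- function(patients, config = texture_config()) {
  mat <- t(vapply(patients, function(p) extract_all(p$roi, config),
                  numeric(730L)))
  out <- data.frame(id = vapply(patients, `[[`, character(1), "id"), mat,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
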