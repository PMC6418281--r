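# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, rle over explicit lines) so they share
# no code path with the package implementation.

# Build an roi_image directly (bypasses the >= 16 cell gate of apply_mask,
# which unit fixtures are allowed to undercut).
make_roi <- function(pixels, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, mask = mask, n_roi = sum(mask)),
            class = "roi_image")
}

make_quantized <- function(levels, Ng, mask = NULL) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  if (is.null(mask)) mask <- levels > 0L
  structure(list(levels = levels, Ng = as.integer(Ng), mask = mask),
            class = "quantized_roi")
}

dir_offsets <- list(d0 = c(0L, 1L), d45 = c(-1L, 1L), d90 = c(-1L, 0L),
                    d135 = c(-1L, -1L))

# Brute-force symmetric GLCM counts: loop over every ordered cell pair.
oracle_glcm_counts <- function(levels, mask, direction, Ng) {
  off <- dir_offsets[[direction]]
  out <- matrix(0, Ng, Ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r, c] || !mask[r2, c2]) next
      i <- levels[r, c]; j <- levels[r2, c2]
      out[i, j] <- out[i, j] + 1
      out[j, i] <- out[j, i] + 1
    }
  }
  out
}

# Brute-force GLRLM: enumerate the lines of the direction, break them at
# mask gaps, and count maximal runs with rle.
oracle_glrlm_counts <- function(levels, mask, direction, Ng, maxlen) {
  nr <- nrow(levels); nc <- ncol(levels)
  cells <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  line_id <- switch(direction,
    d0 = cells$r,
    d90 = cells$c,
    d45 = cells$r + cells$c,       # step (-1,+1) keeps r+c constant
    d135 = cells$r - cells$c       # step (-1,-1) keeps r-c constant
  )
  out <- matrix(0, Ng, maxlen)
  for (id in unique(line_id)) {
    sel <- cells[line_id == id, , drop = FALSE]
    sel <- sel[order(sel$c, sel$r), , drop = FALSE]
    vals <- mapply(function(r, c) if (mask[r, c]) levels[r, c] else NA_integer_,
                   sel$r, sel$c)
    rl <- rle(vals)
    for (k in seq_along(rl$lengths)) {
      if (is.na(rl$values[k])) next
      out[rl$values[k], rl$lengths[k]] <- out[rl$values[k], rl$lengths[k]] + 1
    }
  }
  out
}

# O(n^2) Harrell C-index with explicit pair enumeration.
oracle_cindex <- function(risk, time, event) {
  conc <- tied <- comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j || !(time[i] < time[j])) next
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / comp
}

random_masked_grid <- function(nr, nc, Ng, p_mask = 0.8) {
  list(
    levels = matrix(sample.int(Ng, nr * nc, replace = TRUE), nr, nc),
    mask = matrix(runif(nr * nc) < p_mask, nr, nc)
  )
}
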