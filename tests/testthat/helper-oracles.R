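# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation (threshold-descent region
# growing vs union-find flooding; direct formulas vs fitted objects).

# -- 8-connected morphological helpers (vectorized shifts) -------------------

shift_or <- function(b, dr, dc) {
  n <- nrow(b); m <- ncol(b)
  out <- matrix(FALSE, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- b[rs - dr, cs - dc]
  out
}

dilate8 <- function(b) {
  v <- b | shift_or(b, 1, 0) | shift_or(b, -1, 0)
  v | shift_or(v, 0, 1) | shift_or(v, 0, -1)
}

max_filter8 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  shift_val <- function(dr, dc) {
    out <- matrix(-Inf, n, m)
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(m, m + dc)
    out[rs, cs] <- img[rs - dr, cs - dc]
    out
  }
  out <- matrix(-Inf, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_val(dr, dc))
  }
  out
}

# -- brute-force prominence oracle -------------------------------------------
# For every local-maximum plateau: grow the super-level region of the peak
# while descending the threshold through the image's values; the saddle is
# the first level at which the region touches a strictly higher pixel
# (image minimum if that never happens). Keep prominence > tol.

oracle_prominence_maxima <- function(img, tol) {
  n <- nrow(img); m <- ncol(img)
  has_higher <- max_filter8(img) > img
  visited <- matrix(FALSE, n, m)
  vals <- sort(unique(as.numeric(img)), decreasing = TRUE)
  out <- NULL
  for (p in seq_len(n * m)) {
    if (visited[p]) next
    v <- img[p]
    # flood the equal-value plateau containing p
    plate <- matrix(FALSE, n, m); plate[p] <- TRUE
    repeat {
      grown <- dilate8(plate) & (img == v)
      if (identical(grown, plate)) break
      plate <- grown
    }
    visited[plate] <- TRUE
    if (any(has_higher[plate])) next       # not a local-maximum plateau
    region <- plate
    sad <- min(img)
    for (t in vals[vals <= v]) {
      inr <- img >= t
      repeat {
        grown <- dilate8(region) & inr
        if (identical(grown, region)) break
        region <- grown
      }
      if (any(img[region] > v)) { sad <- t; break }
    }
    if (v - sad > tol) {
      rows <- row(img)[plate]; cols <- col(img)[plate]
      out <- rbind(out, data.frame(row = floor(mean(rows) + 0.5),
                                   col = floor(mean(cols) + 0.5),
                                   peak_value = v, prominence = v - sad))
    }
  }
  out
}

# -- one-line RMSD oracle -----------------------------------------------------

oracle_rmsd <- function(y, t_, slope, intercept, window) {
  sqrt(mean((y[window] - (intercept + slope * t_[window]))^2))
}

# -- small builders -----------------------------------------------------------

make_trace <- function(ratio, dt = 4, id = "c1") ratio_trace(ratio, dt, cell_id = id)

make_channels <- function(ex410, ex490, id = "c1") {
  structure(list(cell_id = id, ex410 = ex410, ex490 = ex490),
            class = "channel_traces")
}

# Gaussian spot painter for focus tests
paint_spot <- function(img, r0, c0, amp, sigma = 1.5) {
  n <- nrow(img); m <- ncol(img)
  for (r in 1:n) for (c in 1:m) {
    img[r, c] <- img[r, c] + amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2))
  }
  img
}
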