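# Internal geometry helpers shared by the synthetic generator and the
# graph module. All polylines are n x 2 matrices, columns (x, y).

# Euclidean length of a polyline (sum of successive steps).
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# Resample a polyline at (approximately) equal spacing, keeping both
# endpoints exactly. Returns at least the two endpoints.
resample_polyline <- function(pts, spacing) {
  stopifnot(spacing > 0)
  if (nrow(pts) < 2) return(pts)
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total == 0) return(pts[c(1, nrow(pts)), , drop = FALSE])
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  at <- seq(0, total, length.out = n_out)
  cbind(approx(s, pts[, 1], xout = at, ties = "ordered")$y,
        approx(s, pts[, 2], xout = at, ties = "ordered")$y)
}

# Moving-average smoothing of interior points; endpoints are fixed so a
# collinear polyline stays exactly collinear and chord lengths are
# unaffected. `window` is the half-width in points.
smooth_polyline <- function(pts, window = 2L) {
  n <- nrow(pts)
  if (n < 2 * window + 3 || window < 1) return(pts)
  out <- pts
  k <- 2L * window + 1L
  kern <- rep(1 / k, k)
  for (j in 1:2) {
    sm <- stats::filter(pts[, j], kern, sides = 2)
    idx <- (window + 1L):(n - window)
    out[idx, j] <- sm[idx]
  }
  out
}

# Arc length of a traced digital centerline, in pixels. Raw 8-connected
# chain-code sums overestimate oblique curves by up to ~8%, so the path is
# smoothed (endpoints fixed) and resampled before measuring. Exact on
# collinear paths; within ~1% on rasterized circles.
measure_arc_px <- function(pts_px, smooth_window = 2L, spacing_px = 2) {
  if (nrow(pts_px) < 2) return(0)
  p <- smooth_polyline(pts_px, smooth_window)
  p <- resample_polyline(p, spacing_px)
  polyline_length(p)
}

rotate2 <- function(v, angle_rad) {
  c(cos(angle_rad) * v[1] - sin(angle_rad) * v[2],
    sin(angle_rad) * v[1] + cos(angle_rad) * v[2])
}

# Minimum distance from a point to a segment chord p0->p1.
dist_point_segment <- function(q, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) return(sqrt(sum((q - p0)^2)))
  t <- max(0, min(1, sum((q - p0) * v) / L2))
  sqrt(sum((q - (p0 + t * v))^2))
}

# Paint a tube (disk swept along a polyline) into a logical matrix.
# Coordinates are in pixel units: pixel [row r, col c] has center
# (x = c - 0.5, y = r - 0.5). A pixel is set iff the distance from its
# center to some resampled centerline point is <= radius_px.
paint_tube <- function(mask, pts_px, radius_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- resample_polyline(pts_px, spacing = max(0.4, radius_px / 4))
  r <- radius_px
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    c0 <- max(1L, ceiling(x - r + 0.5)); c1 <- min(nc, floor(x + r + 0.5))
    r0 <- max(1L, ceiling(y - r + 0.5)); r1 <- min(nr, floor(y + r + 0.5))
    if (c0 > c1 || r0 > r1) next
    dx2 <- ((c0:c1) - 0.5 - x)^2
    dy2 <- ((r0:r1) - 0.5 - y)^2
    hit <- outer(dy2, dx2, "+") <= r * r
    blk <- mask[r0:r1, c0:c1, drop = FALSE]
    mask[r0:r1, c0:c1] <- blk | hit
  }
  mask
}

# Separable Gaussian blur with reflect padding.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  blur_axis <- function(mm, along_rows) {
    if (!along_rows) mm <- t(mm)
    n <- nrow(mm)
    idx <- c(k:1, 1:n, n:(n - k + 1))
    padded <- mm[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(w)) out <- out + w[j] * padded[(j - 1) + 1:n, , drop = FALSE]
    if (!along_rows) out <- t(out)
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

# Shift a matrix by integer offsets (dr, dc) with reflect padding:
# result[r, c] = m[r + dr, c + dc] with out-of-range indices reflected.
shift_reflect <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- (1:nr) + dr
  ci <- (1:nc) + dc
  ri <- ifelse(ri < 1, 2 - ri, ifelse(ri > nr, 2 * nr - ri, ri))
  ci <- ifelse(ci < 1, 2 - ci, ifelse(ci > nc, 2 * nc - ci, ci))
  m[ri, ci, drop = FALSE]
}

# Sample a matrix at a constant fractional offset (dx, dy) in pixel units
# via bilinear interpolation of four integer shifts (reflect padding).
# Positive dx samples to the right (larger col), dy downward (larger row).
shift_bilinear <- function(m, dx, dy) {
  c0 <- floor(dx); r0 <- floor(dy)
  fx <- dx - c0; fy <- dy - r0
  (1 - fy) * (1 - fx) * shift_reflect(m, r0, c0) +
    (1 - fy) * fx     * shift_reflect(m, r0, c0 + 1L) +
    fy * (1 - fx)     * shift_reflect(m, r0 + 1L, c0) +
    fy * fx           * shift_reflect(m, r0 + 1L, c0 + 1L)
}

# 2x bilinear upsampling of a binary mask, thresholded at 0.5. Along an
# oblique tube the boundary staircase encodes the sub-pixel offset of the
# true boundary; interpolation recovers part of it, which tightens
# distance-transform radius estimates for vessels near one pixel wide.
upsample2_bilinear <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  mm <- m * 1
  idx <- function(n) {
    pos <- ((1:(2 * n)) - 0.5) / 2 + 0.5
    i0 <- floor(pos - 0.5)
    list(a = pmax(1, pmin(n, i0)), b = pmax(1, pmin(n, i0 + 1)),
         f = pos - 0.5 - i0)
  }
  ir <- idx(n1); ic <- idx(n2)
  t1 <- mm[ir$a, , drop = FALSE] * (1 - ir$f) + mm[ir$b, , drop = FALSE] * ir$f
  t2 <- t(t(t1[, ic$a, drop = FALSE]) * (1 - ic$f)) +
    t(t(t1[, ic$b, drop = FALSE]) * ic$f)
  t2 > 0.5
}

# Tiny FNV-1a hash of a character scalar, for config provenance stamps.
# 32-bit arithmetic done in doubles: xor only touches the low byte, and
# the prime multiply is split so no intermediate exceeds 2^53.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
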