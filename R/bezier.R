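# Closed composite cubic Bezier interpolation of contour polylines.
#
# Tangents follow the Catmull-Rom rule m_i = (p_{i+1} - p_{i-1}) / 2, which
# gives a C1 closed curve through every input point. The curve is sampled
# densely, then re-sampled at equal arc length.

# Evaluate one cubic Bezier segment at parameters t (vector)
bezier_segment <- function(b0, b1, b2, b3, t) {
  u <- 1 - t
  cbind(u^3 * b0[1] + 3 * u^2 * t * b1[1] + 3 * u * t^2 * b2[1] + t^3 * b3[1],
        u^3 * b0[2] + 3 * u^2 * t * b1[2] + 3 * u * t^2 * b2[2] + t^3 * b3[2])
}

# Dense sampling of the closed composite curve through points `p` (n x 2).
# Returns `per_seg * n` points starting at p[1, ] (t = 0 of segment 1).
bezier_closed_dense <- function(p, per_seg = 24L) {
  n <- nrow(p)
  pm <- p[c(n, seq_len(n - 1L)), , drop = FALSE]   # p_{i-1}
  pp <- p[c(seq_len(n)[-1], 1L), , drop = FALSE]   # p_{i+1}
  m <- (pp - pm) / 2
  ts <- (seq_len(per_seg) - 1L) / per_seg
  out <- matrix(0, n * per_seg, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    b0 <- p[i, ]; b3 <- p[j, ]
    b1 <- b0 + m[i, ] / 3; b2 <- b3 - m[j, ] / 3
    out[(i - 1L) * per_seg + seq_len(per_seg), ] <-
      bezier_segment(b0, b1, b2, b3, ts)
  }
  out
}

# Resample a closed dense polyline to n_out points at equal arc length,
# keeping the first point fixed.
resample_equal_arclength <- function(dense, n_out) {
  d <- sqrt(rowSums((rbind(dense[-1, , drop = FALSE],
                           dense[1, , drop = FALSE]) - dense)^2))
  s <- c(0, cumsum(d))                 # length nrow+1, s[end] = perimeter
  total <- s[length(s)]
  target <- total * (seq_len(n_out) - 1L) / n_out
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(dense))
  s0 <- s[idx]
  frac <- ifelse(d[idx] > 0, (target - s0) / d[idx], 0)
  nxt <- ifelse(idx == nrow(dense), 1L, idx + 1L)
  dense[idx, , drop = FALSE] +
    (dense[nxt, , drop = FALSE] - dense[idx, , drop = FALSE]) * frac
}

#' Up-sample a slice contour with a closed composite cubic Bezier
#'
#' Fits a C1 closed composite cubic Bezier through the contour points
#' (Catmull-Rom tangents) and returns `n_out` points at equal arc length
#' along the curve, starting at the first input point. The fitted curve
#' passes through every input point by construction.
#'
#' @param contour an [slice_contour()].
#' @param n_out number of output points (>= number of input points).
#' @return a new `lv_slice_contour` with `n_out` points.
#' @export
resample_contour_bezier <- function(contour, n_out) {
  p <- contour$points
  if (n_out < nrow(p))
    stop_lv("reconstruct", "n_out must be >= number of input points")
  dense <- bezier_closed_dense(p, per_seg = max(8L,
                                                ceiling(8 * n_out / nrow(p))))
  out <- resample_equal_arclength(dense, n_out)
  if (!polyline_is_simple(out[seq(1, nrow(out),
                                  length.out = min(nrow(out), 256L)), ,
                               drop = FALSE]))
    stop_lv("reconstruct", "resampled contour self-intersects ",
            "(degenerate input geometry on slice ", contour$slice_index, ")")
  slice_contour(contour$slice_index, contour$z, contour$surface,
                contour$phase, out, check = FALSE)
}

# Resample a contour at n equally spaced azimuths about its area centroid,
# starting at `ref_angle`. Assumes the contour is star-shaped about the
# centroid (true for LV short-axis contours). Returns an n x 2 matrix.
resample_contour_angular <- function(contour, n, ref_angle = 0) {
  dense <- bezier_closed_dense(contour$points, per_seg = 24L)
  ctr <- polygon_centroid(contour$points)
  rel <- sweep(dense, 2, ctr)
  th <- atan2(rel[, 2], rel[, 1])
  r <- sqrt(rowSums(rel^2))
  ord <- order(th)
  th <- th[ord]; r <- r[ord]
  # wrap for interpolation across the -pi/pi seam
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r_ext <- c(r[length(r)], r, r[1])
  tgt <- ref_angle + 2 * pi * (seq_len(n) - 1L) / n
  tgt <- ((tgt + pi) %% (2 * pi)) - pi
  ri <- stats::approx(th_ext, r_ext, xout = tgt, ties = "ordered")$y
  cbind(ctr[1] + ri * cos(tgt), ctr[2] + ri * sin(tgt))
}
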