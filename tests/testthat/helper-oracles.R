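# Independent brute-force oracles, deliberately coded with different
# primitives than the package (dot products / acos instead of atan2
# differences) so that agreement is evidence, not tautology.

oracle_seg_lengths <- function(pts) {
  out <- numeric(nrow(pts) - 1)
  for (i in seq_len(nrow(pts) - 1))
    out[i] <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
  out
}

oracle_seg_orientations <- function(pts) {
  out <- numeric(nrow(pts) - 1)
  for (i in seq_len(nrow(pts) - 1)) {
    v <- c(pts[i + 1, 1] - pts[i, 1], -(pts[i + 1, 2] - pts[i, 2]))
    a <- acos(pmin(1, pmax(-1, v[1] / sqrt(sum(v^2))))) * 180 / pi
    if (v[2] < 0) a <- 360 - a
    out[i] <- a %% 180
  }
  out
}

oracle_vertex_angularities <- function(pts) {
  n_seg <- nrow(pts) - 1
  if (n_seg < 2) return(numeric(0))
  out <- numeric(n_seg - 1)
  for (i in seq_len(n_seg - 1)) {
    u <- pts[i + 1, ] - pts[i, ]
    v <- pts[i + 2, ] - pts[i + 1, ]
    cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    turn <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    out[i] <- turn / ((sqrt(sum(u^2)) + sqrt(sum(v^2))) / 2)
  }
  out
}

oracle_folded_mean <- function(pts) {
  th <- oracle_seg_orientations(pts)
  thf <- pmin(th, 180 - th)
  w <- oracle_seg_lengths(pts)
  sum(thf * w) / sum(w)
}

random_polyline <- function(max_pts = 12) {
  n <- sample(2:max_pts, 1)
  repeat {
    pts <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    if (all(oracle_seg_lengths(pts) > 0)) return(pts)
  }
}

# small drawing builders used across test files
square_wave_drawing <- function() {
  # two contours on a 100x100 canvas with a mix of turns
  c1 <- contour(cbind(c(10, 30, 30, 50), c(10, 10, 30, 30)), id = "c1")
  c2 <- contour(cbind(c(60, 90), c(80, 50)), id = "c2")
  line_drawing(list(c1, c2), 100, 100)
}

translate_drawing <- function(d, dx, dy) {
  cts <- lapply(d$contours, function(ct)
    contour(cbind(ct$points[, 1] + dx, ct$points[, 2] + dy), id = ct$id))
  line_drawing(cts, d$canvas_width + abs(dx), d$canvas_height + abs(dy))
}

rotate_drawing_90 <- function(d) {
  # 90 degree visual rotation within canvas: (x, y) -> (y, W - x) maps a
  # visual-space rotation into image coordinates
  cts <- lapply(d$contours, function(ct)
    contour(cbind(ct$points[, 2], d$canvas_width - ct$points[, 1]),
            id = ct$id))
  line_drawing(cts, d$canvas_height, d$canvas_width)
}

scale_drawing <- function(d, s) {
  cts <- lapply(d$contours, function(ct)
    contour(ct$points * s, id = ct$id))
  line_drawing(cts, d$canvas_width * s, d$canvas_height * s)
}
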