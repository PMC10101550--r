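# shared fixtures and independent oracles

square_arena <- function() {
  make_arena(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
             rbind(c(50, 0), c(50, 100)))
}

# independent point-in-polygon oracle: winding-angle summation, written
# differently from the package's crossing-number implementation
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vx <- poly[, 1L] - px; vy <- poly[, 2L] - py
  # on-boundary check by distance to each segment
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1L]; ay <- poly[i, 2L]
    bx <- poly[j, 1L]; by <- poly[j, 2L]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2
    t <- min(1, max(0, t))
    dx <- px - (ax + t * (bx - ax)); dy <- py - (ay + t * (by - ay))
    if (dx * dx + dy * dy < 1e-18) return(TRUE)
  }
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ang <- ang + atan2(vx[i] * vy[j] - vy[i] * vx[j],
                       vx[i] * vx[j] + vy[i] * vy[j])
  }
  abs(ang) > pi
}

oracle_side <- function(px, py, arena) {
  if (!oracle_in_polygon(px, py, arena$polygon)) return("outside")
  d <- arena$divider
  s <- (d[2, 2] - d[1, 2]) * (px - d[1, 1]) -
       (d[2, 1] - d[1, 1]) * (py - d[1, 2])
  if (s <= 0) "left" else "right"
}

# exhaustive Otsu oracle: scan every candidate level k/levels and maximize
# the between-class variance computed directly from the data
oracle_otsu <- function(x, levels = 256L) {
  x <- as.numeric(x)
  cand <- seq_len(levels - 1L) / levels
  bcv <- vapply(cand, function(t) {
    g0 <- x[x <= t]; g1 <- x[x > t]
    if (!length(g0) || !length(g1)) return(-Inf)
    w0 <- length(g0) / length(x)
    w0 * (1 - w0) * (mean(g0) - mean(g1))^2
  }, numeric(1L))
  cand[which.max(bcv)]
}

# frame with a dark filled rectangle on a light background
frame_with_square <- function(nr, nc, top, left, size, bg = 0.8, lvl = 0.1) {
  f <- matrix(bg, nr, nc)
  f[top:(top + size - 1L), left:(left + size - 1L)] <- lvl
  f
}

# trajectory with the given number of points per side
counted_trajectory <- function(n_left, n_right, n_outside = 0L,
                               n_missing = 0L) {
  side <- c(rep("left", n_left), rep("right", n_right),
            rep("outside", n_outside), rep("missing", n_missing))
  n <- length(side)
  x <- ifelse(side == "missing", NA_real_, 1)
  trajectory(seq_len(n) * 30L - 30L, x = x, y = x, side = side)
}

# analytic sd of the time-averaged occupancy of the stationary two-state
# chain: autocovariance p(1-p) exp(-theta t), theta = 1/m_I + 1/m_S
occupancy_sd <- function(p, mean_dwell, duration) {
  m_i <- 2 * p * mean_dwell
  m_s <- 2 * (1 - p) * mean_dwell
  theta <- 1 / m_i + 1 / m_s
  sqrt(2 * p * (1 - p) / (theta * duration))
}
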