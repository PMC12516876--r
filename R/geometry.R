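# Planar geometry helpers for spot-density work. Coordinates are um in
# image convention (y down); all predicates are deterministic.

# Signed shoelace area, returned as absolute value.
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-crossing test for two closed segments, used only to reject
# self-intersecting rings; shared endpoints of adjacent edges are ignored
# by the caller.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_self_intersects <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j == i) next
      j2 <- if (j == n) 1L else j + 1L
      # skip edges sharing a vertex
      if (i2 == j || j2 == i) next
      if (segments_cross(v[i, ], v[i2, ], v[j, ], v[j2, ])) return(TRUE)
    }
  }
  FALSE
}

# Even-odd point-in-polygon, boundary inclusive. Boundary hits (point on an
# edge or vertex) are decided exactly with cross products; the crossing count
# uses half-open edges so each vertex is counted once.
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  m <- length(px)
  inside <- logical(m)
  for (p in seq_len(m)) {
    x <- px[p]; y <- py[p]
    on_boundary <- FALSE
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (cross == 0 &&
          x >= min(x1, x2) && x <= max(x1, x2) &&
          y >= min(y1, y2) && y <= max(y1, y2)) {
        on_boundary <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (xi > x) crossings <- crossings + 1L
      }
    }
    inside[p] <- on_boundary || (crossings %% 2L == 1L)
  }
  inside
}
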