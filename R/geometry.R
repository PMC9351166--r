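# Planar polygon primitives. Geometries are stored as a list-column on the
# area tibble: each element is a list of "parts", each part a list of rings,
# each ring an (m x 2) coordinate matrix (not closed; first ring exterior,
# later rings holes). All coordinates are projected planar metres.

# signed area of one ring (shoelace); positive = counter-clockwise
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))  # degenerate ring: fall back to vertex mean
  }
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

# area-weighted centroid of a multipolygon; holes get negative weight
poly_centroid <- function(geom) {
  num <- c(0, 0); den <- 0
  for (part in geom) {
    for (i in seq_along(part)) {
      a <- abs(ring_signed_area(part[[i]]))
      if (i > 1L) a <- -a  # hole
      num <- num + a * ring_centroid(part[[i]])
      den <- den + a
    }
  }
  if (den <= 0) abort("degenerate geometry: zero total area")
  num / den
}

poly_area <- function(geom) {
  a <- 0
  for (part in geom) {
    for (i in seq_along(part)) {
      ra <- abs(ring_signed_area(part[[i]]))
      a <- a + if (i > 1L) -ra else ra
    }
  }
  a
}

# simple self-intersection check: any two non-adjacent edges of a ring cross
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(ring) {
  m <- nrow(ring)
  if (m < 4) return(FALSE)
  idx <- rbind(ring, ring[1, ])
  for (i in seq_len(m - 2)) {
    jmax <- if (i == 1) m - 1 else m
    for (j in seq(i + 2, jmax)) {
      if (segments_cross(idx[i, ], idx[i + 1, ], idx[j, ], idx[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

# point on a ring segment, within tolerance
point_on_ring <- function(px, py, ring, eps = 1e-9) {
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  d2 <- (x1 + t * dx - px)^2 + (y1 + t * dy - py)^2
  any(d2 <= eps^2 * pmax(1, len2))
}

# ray casting; boundary treated as inside (inclusive)
point_in_ring <- function(px, py, ring) {
  if (point_on_ring(px, py, ring)) return(TRUE)
  x <- ring[, 1]; y <- ring[, 2]
  m <- length(x)
  j <- m
  inside <- FALSE
  for (i in seq_len(m)) {
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# inclusive containment in a (multi)polygon with holes
point_in_poly <- function(px, py, geom) {
  for (part in geom) {
    if (point_in_ring(px, py, part[[1]])) {
      in_hole <- FALSE
      for (i in seq_along(part)[-1]) {
        if (point_in_ring(px, py, part[[i]]) && !point_on_ring(px, py, part[[i]])) {
          in_hole <- TRUE
          break
        }
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

poly_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# guard: coordinates that look like lon/lat degrees are refused — all the
# kernel bandwidths and distances in this package are metric
check_projected <- function(x, y, what = "coordinates") {
  if (all(abs(x) <= 360) && all(abs(y) <= 90)) {
    abort(paste0(
      what, " look like longitude/latitude degrees (|x| <= 360, |y| <= 90); ",
      "this package requires projected planar coordinates in metres"
    ))
  }
  invisible(TRUE)
}
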