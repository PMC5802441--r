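# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package internals they check.

# gift-wrapping (Jarvis march) convex hull, counter-clockwise
oracle_gift_wrap <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == n) 1L else p + 1L
    for (r in seq_len(n)) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cross < 0 || (cross == 0 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

# point-in-rectangle scan: assign each point to the cell whose half-open
# rectangle contains it, by looping over all cells
oracle_point_in_rect <- function(lon, lat, cells) {
  out <- rep(NA_character_, length(lon))
  for (i in seq_along(lon)) {
    for (j in seq_len(nrow(cells))) {
      if (lon[i] >= cells$west[j] && lon[i] < cells$east[j] &&
          lat[i] >= cells$south[j] && lat[i] < cells$north[j]) {
        out[i] <- cells$cell_id[j]
        break
      }
    }
  }
  out
}

# cumulative-sum scan for equal-variance breakpoints on one component:
# sort the scores, walk outward from the origin on each side accumulating
# squared-score contributions, and whenever a bin has filled to theta,
# record a boundary midway to the next score and start the next bin
oracle_breakpoints <- function(scores_all, component, theta, origin = 0) {
  total <- sum(unlist(scores_all)^2)
  s <- sort(scores_all[[component]])
  side_breaks <- function(vals) {
    acc <- 0; breaks <- numeric(0)
    for (i in seq_along(vals)) {
      acc <- acc + vals[i]^2 / total
      if (acc >= theta - 1e-12 && i < length(vals)) {
        breaks <- c(breaks, (vals[i] + vals[i + 1]) / 2)
        acc <- 0
      }
    }
    breaks
  }
  pos <- s[s > origin]
  neg <- rev(s[s <= origin])
  sort(c(side_breaks(neg), origin, side_breaks(pos)))
}

# all-pixel scan for nearest-class distance from one point (km, flat
# equidistant-cylindrical metric)
oracle_class_distance <- function(r, class_code, lon0, lat0) {
  kmdeg <- 111.32
  idx <- which(r$values == class_code, arr.ind = TRUE)
  if (nrow(idx) == 0) return(Inf)
  cc <- raster_centres(r, idx[, 1], idx[, 2])
  min(sqrt(((cc$lon - lon0) * kmdeg)^2 + ((cc$lat - lat0) * kmdeg)^2))
}

# Sutherland-Hodgman clip of a polygon by an axis-aligned rectangle;
# returns the clipped area (0 if disjoint)
oracle_rect_clip_area <- function(poly_lon, poly_lat, w, s, e, n) {
  clip <- function(pts, keep, cross) {
    if (nrow(pts) == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(pts)
    for (i in seq_len(m)) {
      a <- pts[i, ]; b <- pts[if (i == m) 1 else i + 1, ]
      ka <- keep(a); kb <- keep(b)
      if (ka) out <- rbind(out, a)
      if (xor(ka, kb)) out <- rbind(out, cross(a, b))
    }
    out
  }
  pts <- cbind(poly_lon, poly_lat)
  ix <- function(a, b, x) c(x, a[2] + (b[2] - a[2]) * (x - a[1]) / (b[1] - a[1]))
  iy <- function(a, b, y) c(a[1] + (b[1] - a[1]) * (y - a[2]) / (b[2] - a[2]), y)
  pts <- clip(pts, function(p) p[1] >= w, function(a, b) ix(a, b, w))
  pts <- clip(pts, function(p) p[1] <= e, function(a, b) ix(a, b, e))
  pts <- clip(pts, function(p) p[2] >= s, function(a, b) iy(a, b, s))
  pts <- clip(pts, function(p) p[2] <= n, function(a, b) iy(a, b, n))
  if (nrow(pts) < 3) return(0)
  m <- nrow(pts)
  j <- c(m, seq_len(m - 1))
  abs(sum(pts[j, 1] * pts[, 2] - pts[, 1] * pts[j, 2])) / 2
}
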