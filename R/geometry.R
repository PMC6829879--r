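#' Minimal distance between two line segments
#'
#' Smallest Euclidean distance between any point of segment `a` and any
#' point of segment `b` (both closed). Zero exactly when the segments touch
#' or cross. A zero-length segment is treated as a point.
#'
#' @param a,b Segments as length-4 numeric vectors `c(x1, y1, x2, y2)` or
#'   one-row data frames with those columns.
#' @return Non-negative distance in pixels.
#' @export
segment_min_distance <- function(a, b) {
  a <- as_seg_vec(a)
  b <- as_seg_vec(b)
  seg_pair_min_dist(a[1], a[2], a[3], a[4], b[1], b[2], b[3], b[4])
}

#' Included angle between two segments
#'
#' Acute angle between the undirected directions of two segments, in
#' degrees within `[0, 90]`. Directions 10 and 170 degrees yield 20.
#'
#' @inheritParams segment_min_distance
#' @return Angle in degrees.
#' @export
included_angle <- function(a, b) {
  a <- as_seg_vec(a)
  b <- as_seg_vec(b)
  ua <- c(a[3] - a[1], a[4] - a[2])
  ub <- c(b[3] - b[1], b[4] - b[2])
  la <- sqrt(sum(ua^2))
  lb <- sqrt(sum(ub^2))
  if (la == 0 || lb == 0) {
    stop("zero-length segment has no direction (undefined-direction error)")
  }
  cosang <- abs(sum(ua * ub)) / (la * lb)
  acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
}

as_seg_vec <- function(s) {
  if (is.data.frame(s)) {
    stopifnot(nrow(s) == 1)
    s <- c(s$x1, s$y1, s$x2, s$y2)
  }
  stopifnot(is.numeric(s), length(s) == 4)
  as.numeric(s)
}

# vectorized point-to-segment distance
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx^2 + dy^2
  # degenerate segments: numerator is 0 too, so t collapses to 0
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(l2, .Machine$double.xmin)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# vectorized segment-segment minimal distance
seg_pair_min_dist <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  o1 <- cross(ax1, ay1, ax2, ay2, bx1, by1)
  o2 <- cross(ax1, ay1, ax2, ay2, bx2, by2)
  o3 <- cross(bx1, by1, bx2, by2, ax1, ay1)
  o4 <- cross(bx1, by1, bx2, by2, ax2, ay2)
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  d <- pmin(
    point_seg_dist(ax1, ay1, bx1, by1, bx2, by2),
    point_seg_dist(ax2, ay2, bx1, by1, bx2, by2),
    point_seg_dist(bx1, by1, ax1, ay1, ax2, ay2),
    point_seg_dist(bx2, by2, ax1, ay1, ax2, ay2)
  )
  ifelse(proper, 0, d)
}

# acute angle in degrees between undirected segment directions, vectorized
seg_pair_angle <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  uax <- ax2 - ax1
  uay <- ay2 - ay1
  ubx <- bx2 - bx1
  uby <- by2 - by1
  la <- sqrt(uax^2 + uay^2)
  lb <- sqrt(ubx^2 + uby^2)
  cosang <- abs(uax * ubx + uay * uby) / (la * lb)
  acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
}
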