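# Polygon primitives for annotation geometry.
#
# A "ring" is a list(x, y) of vertices, open (last vertex != first).
# A "region" is a list of rings as produced by polyclip under the nonzero
# fill rule: outer rings and holes are distinguished by winding direction,
# rings never cross each other. All class regions in an AnnotationSet are
# normalized through a polyclip union so this invariant holds.

ring_area_signed <- function(ring) {
  x <- ring$x; y <- ring$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(ring) {
  c(mean(ring$x), mean(ring$y))
}

region_area <- function(region) {
  if (length(region) == 0) return(0)
  abs(sum(vapply(region, ring_area_signed, numeric(1))))
}

rect_ring <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Clipper works on an integer grid; fixing it at 2^-20 px makes results
# on integer-coordinate inputs (tile rectangles, aligned annotations)
# exact while resolving curved inputs to ~1e-6 px.
CLIP_EPS <- 2^-20

region_op <- function(a, b, op) {
  if (length(a) == 0) return(if (op == "union") b else list())
  if (length(b) == 0) return(if (op %in% c("union", "minus")) a else list())
  polyclip::polyclip(a, b, op = op, fillA = "nonzero", fillB = "nonzero",
                     x0 = 0, y0 = 0, eps = CLIP_EPS)
}

region_union_self <- function(rings) {
  if (length(rings) <= 1) return(rings)
  polyclip::polyclip(rings, rings, op = "union", fillA = "nonzero",
                     fillB = "nonzero", x0 = 0, y0 = 0, eps = CLIP_EPS)
}

region_intersect_area <- function(region, clip) {
  region_area(region_op(region, clip, "intersection"))
}

# Exact self-intersection test for a single ring: any two non-adjacent
# edges that properly cross, or adjacent edges that overlap.
ring_is_simple <- function(ring) {
  n <- length(ring$x)
  if (n < 3) return(FALSE)
  x <- ring$x; y <- ring$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  seg_intersect <- function(i, j) {
    d1 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
    d2 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
    d3 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d4 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    FALSE
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in seq(i + 2L, jmax)) {
      if (seg_intersect(i, j)) return(FALSE)
    }
  }
  TRUE
}

# Vectorized point-in-region test (pixel centres etc.). Even-odd crossing
# per ring, signed by winding, summed: winding > 0 means inside under the
# nonzero rule, which on polyclip-normalized regions is plain membership
# with holes excluded.
points_in_region <- function(px, py, region) {
  total <- integer(length(px))
  for (ring in region) {
    s <- sign(ring_area_signed(ring))
    if (s == 0) next
    x <- ring$x; y <- ring$y
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    inside <- logical(length(px))
    for (e in seq_along(x)) {
      crosses <- (y[e] > py) != (y2[e] > py)
      if (any(crosses)) {
        xi <- x[e] + (py[crosses] - y[e]) * (x2[e] - x[e]) / (y2[e] - y[e])
        hit <- logical(sum(crosses))
        hit[px[crosses] < xi] <- TRUE
        inside[crosses] <- xor(inside[crosses], hit)
      }
    }
    total <- total + s * as.integer(inside)
  }
  total > 0
}
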