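# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation's code paths: plain loops and first-principles
# formulas only.

# Grid oracle: enumerate every valid top-left offset directly.
oracle_grid <- function(width, height, tile_size, overlap) {
  stride <- tile_size - floor(overlap * tile_size)
  xs <- 0
  while (utils::tail(xs, 1) + stride + tile_size <= width)
    xs <- c(xs, utils::tail(xs, 1) + stride)
  ys <- 0
  while (utils::tail(ys, 1) + stride + tile_size <= height)
    ys <- c(ys, utils::tail(ys, 1) + stride)
  cols <- sum(xs + tile_size <= width)
  rows <- sum(ys + tile_size <= height)
  list(cols = cols, rows = rows)
}

# Otsu oracle: exhaustive search over all 256 candidate thresholds,
# computing the between-class variance from scratch each time.
oracle_otsu <- function(counts) {
  n <- sum(counts)
  best <- -Inf; best_t <- NA
  for (t in 0:255) {
    lo <- counts[1:(t + 1)]
    hi <- if (t < 255) counts[(t + 2):256] else numeric(0)
    n0 <- sum(lo); n1 <- sum(hi)
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * lo) / n0
    mu1 <- sum(((t + 1):255) * hi) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best + 1e-9 * max(best, 1)) { best <- v; best_t <- t }
  }
  best_t
}

# Triangle oracle: explicit geometric construction — rotate each candidate
# point into the peak-tail line frame and take the height.
oracle_triangle <- function(counts) {
  occ <- which(counts > 0) - 1L
  peak <- which.max(counts) - 1L
  lo <- min(occ); hi <- max(occ)
  tail_bin <- if ((peak - lo) > (hi - peak)) lo else hi
  span <- if (tail_bin >= peak) peak:tail_bin else tail_bin:peak
  p1 <- c(peak, counts[peak + 1]); p2 <- c(tail_bin, 0)
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  best <- -Inf; best_b <- NA
  for (b in span) {
    v <- c(b, counts[b + 1]) - p1
    height <- sqrt(max(sum(v^2) - sum(v * u)^2, 0))
    if (height > best + 1e-9 * max(best, 1)) { best <- height; best_b <- b }
  }
  best_b
}

random_histogram <- function() {
  counts <- integer(256)
  for (m in seq_len(sample(1:4, 1))) {
    mu <- sample(0:255, 1); sd <- runif(1, 2, 40)
    v <- round(stats::rnorm(sample(200:2000, 1), mu, sd))
    v <- v[v >= 0 & v <= 255]
    counts <- counts + tabulate(v + 1L, nbins = 256)
  }
  if (sum(counts > 0) < 2) counts[c(10, 200)] <- counts[c(10, 200)] + 5L
  counts
}

# Star-shaped simple polygon around a centre: random radii over sorted
# angles; simple by construction.
random_star_polygon <- function(cx, cy, rmin, rmax, n = 12) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Monte-Carlo area of {inside any of outer rings} minus {inside any hole},
# by rejection sampling over a bounding box. Rings are plain vertex lists.
mc_region_area <- function(outers, holes, n = 4e5) {
  xs <- unlist(lapply(c(outers, holes), `[[`, "x"))
  ys <- unlist(lapply(c(outers, holes), `[[`, "y"))
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  px <- stats::runif(n, x0, x1); py <- stats::runif(n, y0, y1)
  pip <- function(ring) {
    inside <- logical(n)
    m <- length(ring$x)
    for (e in seq_len(m)) {
      j <- if (e == m) 1L else e + 1L
      crosses <- (ring$y[e] > py) != (ring$y[j] > py)
      xi <- ring$x[e] + (py - ring$y[e]) * (ring$x[j] - ring$x[e]) /
        (ring$y[j] - ring$y[e])
      inside <- xor(inside, crosses & px < xi)
    }
    inside
  }
  in_outer <- Reduce(`|`, lapply(outers, pip), logical(n))
  in_hole <- if (length(holes)) Reduce(`|`, lapply(holes, pip), logical(n))
             else logical(n)
  mean(in_outer & !in_hole) * (x1 - x0) * (y1 - y0)
}

# Rasterization oracle for tile overlap: supersampled point-in-polygon
# grid over the tile (level-0 coordinates).
raster_overlap_fraction <- function(x0, y0, size, ring, super = 2L) {
  step <- 1 / super
  cx <- x0 + seq(step / 2, size - step / 2, by = step)
  cy <- y0 + seq(step / 2, size - step / 2, by = step)
  px <- rep(cx, times = length(cy)); py <- rep(cy, each = length(cx))
  inside <- logical(length(px))
  m <- length(ring$x)
  for (e in seq_len(m)) {
    j <- if (e == m) 1L else e + 1L
    crosses <- (ring$y[e] > py) != (ring$y[j] > py)
    xi <- ring$x[e] + (py - ring$y[e]) * (ring$x[j] - ring$x[e]) /
      (ring$y[j] - ring$y[e])
    inside <- xor(inside, crosses & px < xi)
  }
  mean(inside)
}

# Confusion-matrix metric oracle: literal counting.
oracle_metric <- function(gt, pred, metric) {
  tp <- sum(gt & pred); fp <- sum(!gt & pred)
  fn <- sum(gt & !pred); tn <- sum(!gt & !pred)
  div <- function(a, b) if (b == 0) 0 else a / b
  switch(metric,
         accuracy = (tp + tn) / length(gt),
         precision = div(tp, tp + fp),
         recall = div(tp, tp + fn),
         f1 = {
           p <- div(tp, tp + fp); r <- div(tp, tp + fn)
           div(2 * p * r, p + r)
         },
         balanced_accuracy = (div(tp, tp + fn) + div(tn, tn + fp)) / 2)
}

# Pairwise-concordance AUROC oracle.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Per-pixel stitching oracle: for every pixel, scan all tiles for
# coverage and average the contributions.
oracle_stitch <- function(tiles, width, height) {
  # tiles: list of list(x, y, map) with 0-based offsets
  out <- matrix(0, height, width)
  cov <- matrix(0L, height, width)
  for (py in seq_len(height)) {
    for (px in seq_len(width)) {
      vals <- numeric(0)
      for (t in tiles) {
        ts <- nrow(t$map)
        if (px > t$x && px <= t$x + ts && py > t$y && py <= t$y + ts)
          vals <- c(vals, t$map[py - t$y, px - t$x])
      }
      if (length(vals)) {
        out[py, px] <- mean(vals)
        cov[py, px] <- length(vals)
      }
    }
  }
  list(values = out, coverage = cov)
}
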