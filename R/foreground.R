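# Classical foreground detection: Otsu, triangle, fixed intensity cuts.

check_histogram <- function(counts) {
  if (length(counts) != 256 || any(counts < 0) || sum(counts) <= 0)
    sf_stop("A greyscale histogram must be 256 non-negative counts with positive total",
            "slideforge_validation_error")
  if (sum(counts > 0) < 2)
    sf_stop("Degenerate histogram: fewer than 2 occupied bins, no threshold exists",
            "slideforge_degenerate_histogram")
  invisible(counts)
}

#' Otsu threshold of a 256-bin greyscale histogram
#'
#' Returns the bin `t` in 0..255 that maximizes the between-class variance
#' of the split into bins `<= t` and `> t`; ties break toward the lowest
#' bin. Pixels at or below the threshold count as foreground downstream.
#'
#' @param counts 256 non-negative integers (bins 0..255).
#' @return Threshold bin (0-based integer).
#' @export
otsu_threshold <- function(counts) {
  check_histogram(counts)
  p <- counts / sum(counts)
  bins <- 0:255
  w0 <- cumsum(p)                      # weight of class <= t
  mu_cum <- cumsum(p * bins)
  mu_total <- mu_cum[256]
  w1 <- 1 - w0
  # between-class variance; undefined where a class is empty
  num <- (mu_total * w0 - mu_cum)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  # exact ties (e.g. symmetric histograms) resolve to the lowest bin;
  # the tolerance absorbs floating-point noise in the cumulative sums
  m <- max(sigma_b)
  as.integer(which(sigma_b >= m - 1e-9 * max(m, 1))[1] - 1L)
}

#' Triangle threshold of a 256-bin greyscale histogram
#'
#' Draws the line from the histogram peak `(b_peak, count_peak)` to the
#' empty end of the longer tail `(b_tail, 0)` and returns the bin between
#' them whose histogram point is farthest (perpendicular distance) from
#' that line; ties break toward the lowest bin. Suited to strongly
#' unimodal histograms such as the bright-background peak of a slide.
#'
#' @inheritParams otsu_threshold
#' @return Threshold bin (0-based integer).
#' @export
triangle_threshold <- function(counts) {
  check_histogram(counts)
  occupied <- which(counts > 0) - 1L
  peak <- as.integer(which.max(counts) - 1L)
  lo <- min(occupied); hi <- max(occupied)
  # tail = the occupied extreme farther from the peak (ties: right tail,
  # the bright side, which is where slide backgrounds sit)
  tail_bin <- if ((peak - lo) > (hi - peak)) lo else hi
  span <- if (tail_bin >= peak) peak:tail_bin else tail_bin:peak
  # perpendicular distance from (b, counts[b]) to the peak-tail line
  dx <- tail_bin - peak
  dy <- 0 - counts[peak + 1L]
  d <- abs(dx * (counts[span + 1L] - counts[peak + 1L]) -
           dy * (span - peak)) / sqrt(dx^2 + dy^2)
  m <- max(d)
  as.integer(span[which(d >= m - 1e-9 * max(m, 1))[1]])
}

#' Detect foreground tiles by greyscale thresholding
#'
#' Computes the greyscale histogram of a chosen (typically low-resolution)
#' pyramid level, derives Otsu and triangle thresholds from it, and maps
#' the result onto the working tile grid: each tile records its mean
#' greyscale intensity on a 0--100 scale (0 black, 100 white) measured on
#' the detection level, and a pass/fail flag per method (tile mean on the
#' 0--255 scale at or below the method's threshold). Downstream filters
#' accept `'otsu'`, `'triangle'`, or an integer cut 0--100 (a tile passes
#' an integer cut when its 0--100 mean is at or below it, darker = tissue).
#'
#' @param slide A slide with tile properties set.
#' @param level 0-based pyramid level on which to measure intensities.
#' @return The slide with `foreground_mean` and `foreground_pass` filled
#'   for every tile and the thresholds stored in `slide$foreground`.
#' @export
detect_foreground <- function(slide, level = nrow(slide$levels) - 1L) {
  require_tiling(slide)
  img <- level_image(slide, level)
  grey <- rgb_to_grey255(img)
  counts <- tabulate(pmin(pmax(floor(grey), 0), 255) + 1L, nbins = 256)
  thr <- tryCatch(
    list(otsu = otsu_threshold(counts), triangle = triangle_threshold(counts)),
    slideforge_degenerate_histogram = function(e) NULL)
  if (is.null(thr)) {
    sf_warn("No foreground found: the detection level is a single intensity; all tiles fail",
            "slideforge_no_foreground")
    thr <- list(otsu = -1L, triangle = -1L)  # nothing is <= -1
  }
  # detection-level coords of each working tile, via the downsample ratio
  ratio <- slide$downsample[level + 1L] / slide$downsample[slide$level + 1L]
  dh <- nrow(grey); dw <- ncol(grey)
  for (k in seq_along(slide$tiles)) {
    t <- slide$tiles[[k]]
    x0 <- max(0L, as.integer(floor(t$x / ratio)))
    y0 <- max(0L, as.integer(floor(t$y / ratio)))
    x1 <- min(dw, max(x0 + 1L, as.integer(ceiling((t$x + slide$tile_size) / ratio))))
    y1 <- min(dh, max(y0 + 1L, as.integer(ceiling((t$y + slide$tile_size) / ratio))))
    m <- mean(grey[(y0 + 1L):y1, (x0 + 1L):x1])
    slide$tiles[[k]]$foreground_mean <- m / 2.55
    slide$tiles[[k]]$foreground_pass <- list(
      otsu = m <= thr$otsu, triangle = m <= thr$triangle)
  }
  slide$foreground <- list(otsu = thr$otsu, triangle = thr$triangle,
                           level = as.integer(level))
  slide
}

# Does a tile record pass the given foreground filter?
# filter: NULL (pass), 'otsu', 'triangle', or a numeric cut on the 0-100
# mean-intensity scale.
passes_foreground <- function(rec, filter) {
  if (is.null(filter)) return(TRUE)
  if (is.character(filter)) {
    if (!filter %in% c("otsu", "triangle"))
      sf_stop(sprintf("Unknown foreground filter '%s' (use 'otsu', 'triangle', or an integer 0-100)",
                      filter), "slideforge_validation_error")
    if (length(rec$foreground_pass) == 0)
      sf_stop("No foreground detection found in slide. Use detect_foreground() to generate it",
              "slideforge_state_error")
    return(isTRUE(rec$foreground_pass[[filter]]))
  }
  check_fraction(filter, "foreground_filter", 0, 100)
  if (is.na(rec$foreground_mean))
    sf_stop("No foreground detection found in slide. Use detect_foreground() to generate it",
            "slideforge_state_error")
  rec$foreground_mean <= filter
}
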