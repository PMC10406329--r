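# Internal helpers: error conditions, validation, image conversions.

sf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "slideforge_error"),
                      call = call))
}

sf_warn <- function(msg, class = "slideforge_warning") {
  warning(warningCondition(msg, class = c(class, "slideforge_warning")))
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok)
    sf_stop(sprintf("`%s` must be a fraction in %s%g, %g%s, got %s",
                    name, if (lo_open) "(" else "[", lo, hi,
                    if (hi_open) ")" else "]",
                    paste(format(x), collapse = ", ")),
            "slideforge_validation_error")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x == floor(x) && x >= min
  if (!ok)
    sf_stop(sprintf("`%s` must be an integer >= %d", name, min),
            "slideforge_validation_error")
  invisible(as.integer(x))
}

# Luma greyscale on the 0-255 scale from an (h, w, 3) array in [0, 1].
rgb_to_grey255 <- function(img) {
  255 * (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

# Quantize [0,1] image to the uint8 grid (k/255 values), as written to disk.
quantize_uint8 <- function(img) {
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

# 2x2 mean pooling; odd trailing row/col dropped (floor halving).
mean_pool2 <- function(img) {
  h <- dim(img)[1] %/% 2L
  w <- dim(img)[2] %/% 2L
  out <- array(0, dim = c(h, w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[seq_len(2L * h), seq_len(2L * w), ch]
    out[, , ch] <- (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4
  }
  out
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
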