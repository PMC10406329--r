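#' Open a pyramidal whole-slide image
#'
#' Reads a multi-resolution raster (a pyramidal/multi-page TIFF, or a
#' single-page image treated as a one-level pyramid) and returns a slide
#' object holding the level table, per-level downsample factors, and the
#' pixel data. Level 0 is the highest-resolution level; each level's
#' downsample factor relates its pixel coordinates to level 0.
#'
#' @param path Path to the slide image.
#' @param level 0-based pyramid level to make active; tiling and tile reads
#'   operate at the active level.
#' @return An object of class `slideforge_slide` with fields `path`,
#'   `levels` (data frame of `width`/`height` per level), `downsample`,
#'   `level` (active, 0-based), and an initially empty tile dictionary.
#' @details Pages of a multi-page TIFF are sorted by decreasing width so
#'   level 0 always has the largest dimensions. Files the image backend
#'   cannot decode raise an incompatible-image error.
#' @examples
#' \dontrun{
#' sl <- open_slide("slide.tiff", level = 0)
#' sl <- set_tile_properties(sl, tile_size = 500)
#' }
#' @export
open_slide <- function(path, level = 0) {
  if (!file.exists(path))
    sf_stop(sprintf("Slide file not found: %s", path),
            "slideforge_io_error")
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE)),
    error = function(e) NULL)
  if (is.null(pages) || length(pages) == 0)
    sf_stop(paste0("This image is not compatible. `", path,
                   "` could not be decoded as a multi-resolution raster; ",
                   "convert it to a pyramidal TIFF."),
            "slideforge_incompatible_image")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), dim = c(dim(p), 3))
    if (dim(p)[3] > 3) p <- p[, , 1:3, drop = FALSE]
    p
  })
  widths <- vapply(pages, function(p) dim(p)[2], integer(1))
  ord <- order(widths, decreasing = TRUE)
  pages <- pages[ord]
  levels <- data.frame(
    width = vapply(pages, function(p) dim(p)[2], integer(1)),
    height = vapply(pages, function(p) dim(p)[1], integer(1)))
  slide <- structure(list(
    path = normalizePath(path),
    levels = levels,
    downsample = levels$width[1] / levels$width,
    level = 0L,
    images = pages,
    tile_size = NULL, tile_overlap = NULL, stride = NULL,
    grid_cols = NULL, grid_rows = NULL,
    tiles = NULL,
    foreground = NULL,
    tissue_detected = FALSE
  ), class = "slideforge_slide")
  set_active_level(slide, level)
}

set_active_level <- function(slide, level) {
  level <- check_count(level, "level", min = 0L)
  if (level >= nrow(slide$levels))
    sf_stop(sprintf(
      "Level %d is out of range: this slide has %d levels (0 to %d)",
      level, nrow(slide$levels), nrow(slide$levels) - 1L),
      "slideforge_level_error")
  slide$level <- level
  slide
}

#' @export
print.slideforge_slide <- function(x, ...) {
  cat(sprintf("<slideforge_slide> %s\n", basename(x$path)))
  for (l in seq_len(nrow(x$levels)))
    cat(sprintf("  level %d: %d x %d (downsample %.3g)%s\n", l - 1L,
                x$levels$width[l], x$levels$height[l], x$downsample[l],
                if (l - 1L == x$level) "  [active]" else ""))
  if (!is.null(x$tiles))
    cat(sprintf("  tiles: %d x %d grid of %d px, overlap %.2f (%d tiles)\n",
                x$grid_cols, x$grid_rows, x$tile_size, x$tile_overlap,
                length(x$tiles)))
  if (!is.null(x$foreground))
    cat(sprintf("  foreground: otsu %d, triangle %d (level %d)\n",
                x$foreground$otsu, x$foreground$triangle,
                x$foreground$level))
  if (x$tissue_detected) cat("  tissue detection: done\n")
  invisible(x)
}

level_image <- function(slide, level = slide$level) {
  level <- check_count(level, "level", min = 0L)
  if (level >= length(slide$images))
    sf_stop(sprintf("Level %d is out of range (0 to %d)", level,
                    length(slide$images) - 1L), "slideforge_level_error")
  slide$images[[level + 1L]]
}

#' Tile-grid dimensions for an image
#'
#' The number of full tiles of side `tile_size` that fit in a `width` by
#' `height` image when consecutive tiles are offset by
#' `stride = tile_size - floor(tile_overlap * tile_size)` pixels. Tiles
#' that would extend past the image edge are dropped, so every tile lies
#' fully inside the image.
#'
#' @param width,height Image dimensions in pixels.
#' @param tile_size Tile side in pixels (>= 1).
#' @param tile_overlap Overlap between neighbouring tiles as a fraction of
#'   `tile_size`, in `[0, 1)`.
#' @return List with `cols`, `rows`, `stride`.
#' @export
tile_grid_dims <- function(width, height, tile_size, tile_overlap = 0) {
  tile_size <- check_count(tile_size, "tile_size", min = 1L)
  check_fraction(tile_overlap, "tile_overlap", 0, 1, hi_open = TRUE)
  stride <- tile_size - as.integer(floor(tile_overlap * tile_size))
  if (stride < 1L)
    sf_stop("tile_overlap leaves a stride below 1 pixel",
            "slideforge_validation_error")
  cols <- if (width < tile_size) 0L else
    as.integer((width - tile_size) %/% stride + 1L)
  rows <- if (height < tile_size) 0L else
    as.integer((height - tile_size) %/% stride + 1L)
  list(cols = cols, rows = rows, stride = stride)
}

#' Set the tile grid of a slide
#'
#' Enumerates the tile grid at the slide's active level and initializes an
#' empty tile dictionary: one record per tile address, later filled in by
#' foreground detection, tissue detection, annotation overlap and
#' inference. Re-calling replaces the grid and clears all derived fields.
#'
#' @param slide A `slideforge_slide`.
#' @param tile_size Tile side in pixels at the active level.
#' @param tile_overlap Fractional overlap in `[0, 1)` (of `tile_size`).
#' @return The slide with `tiles` populated (row-major order).
#' @export
set_tile_properties <- function(slide, tile_size, tile_overlap = 0) {
  stopifnot(inherits(slide, "slideforge_slide"))
  w <- slide$levels$width[slide$level + 1L]
  h <- slide$levels$height[slide$level + 1L]
  g <- tile_grid_dims(w, h, tile_size, tile_overlap)
  if (g$cols == 0L || g$rows == 0L)
    sf_warn(sprintf(
      "tile_size %d exceeds the active level dimensions (%d x %d); the tile grid is empty",
      as.integer(tile_size), w, h), "slideforge_empty_grid")
  slide$tile_size <- as.integer(tile_size)
  slide$tile_overlap <- tile_overlap
  slide$stride <- g$stride
  slide$grid_cols <- g$cols
  slide$grid_rows <- g$rows
  tiles <- list()
  if (g$cols > 0L && g$rows > 0L) {
    for (row in seq_len(g$rows) - 1L) {
      for (col in seq_len(g$cols) - 1L) {
        tiles[[tile_key(col, row)]] <- list(
          col = col, row = row,
          x = col * g$stride, y = row * g$stride,
          overlap = numeric(0),
          foreground_mean = NA_real_,
          foreground_pass = list(),
          tissue_probs = NULL,
          classifier_probs = NULL,
          segmenter_probs = NULL)
      }
    }
  }
  slide$tiles <- tiles
  slide$foreground <- NULL
  slide$tissue_detected <- FALSE
  slide
}

tile_key <- function(col, row) paste0("c", col, "_r", row)

require_tiling <- function(slide) {
  if (is.null(slide$tiles))
    sf_stop("Tile properties have not been set. Use set_tile_properties() first",
            "slideforge_state_error")
  invisible(slide)
}

#' Tile addresses in iteration order
#'
#' @param slide A slide with tile properties set.
#' @return Data frame of `col`, `row`, `x`, `y` (0-based, pixels at the
#'   active level), row-major: all columns of row 0, then row 1, ...
#' @export
tile_addresses <- function(slide) {
  require_tiling(slide)
  if (length(slide$tiles) == 0)
    return(data.frame(col = integer(0), row = integer(0),
                      x = integer(0), y = integer(0)))
  data.frame(
    col = vapply(slide$tiles, `[[`, integer(1), "col"),
    row = vapply(slide$tiles, `[[`, integer(1), "row"),
    x = vapply(slide$tiles, function(t) as.integer(t$x), integer(1)),
    y = vapply(slide$tiles, function(t) as.integer(t$y), integer(1)),
    row.names = NULL)
}

resolve_address <- function(slide, address) {
  if (is.list(address) || is.data.frame(address))
    address <- c(address$col, address$row)
  if (length(address) != 2 || any(is.na(address)))
    sf_stop("A tile address is a (col, row) pair",
            "slideforge_validation_error")
  col <- as.integer(address[1]); row <- as.integer(address[2])
  if (col < 0L || col >= slide$grid_cols || row < 0L ||
      row >= slide$grid_rows)
    sf_stop(sprintf(
      "Tile address (%d, %d) is outside the %d x %d grid", col, row,
      slide$grid_cols, slide$grid_rows), "slideforge_key_error")
  c(col = col, row = row)
}

#' Read one tile's pixels
#'
#' @param slide A slide with tile properties set.
#' @param address `(col, row)` pair (0-based) or a row of
#'   [tile_addresses()].
#' @return `tile_size` x `tile_size` x 3 array of RGB values in `[0, 1]`
#'   on the uint8 grid (multiples of 1/255), read from the active level.
#' @export
get_tile <- function(slide, address) {
  require_tiling(slide)
  a <- resolve_address(slide, address)
  rec <- slide$tiles[[tile_key(a["col"], a["row"])]]
  img <- level_image(slide)
  img[rec$y + seq_len(slide$tile_size), rec$x + seq_len(slide$tile_size),
      , drop = FALSE]
}

state_version <- 1L

#' Save slide state
#'
#' Persists the tile dictionary, tile properties, level table, source path
#' and active level to a single losslessly-compressed `.pml` state file.
#' Pixel data are not stored; reloading re-opens the source image.
#'
#' @param slide A slide.
#' @param folder Writable directory for the state file.
#' @return Path of the written state file, invisibly.
#' @export
save_state <- function(slide, folder) {
  stopifnot(inherits(slide, "slideforge_slide"))
  if (!dir.exists(folder) || file.access(folder, 2) != 0)
    sf_stop(sprintf("Cannot write state: `%s` is not a writable directory",
                    folder), "slideforge_io_error")
  out <- file.path(folder, paste0(
    tools::file_path_sans_ext(basename(slide$path)), ".pml"))
  state <- list(
    format = "slideforge-state", version = state_version,
    path = slide$path, levels = slide$levels,
    downsample = slide$downsample, level = slide$level,
    tile_size = slide$tile_size, tile_overlap = slide$tile_overlap,
    stride = slide$stride, grid_cols = slide$grid_cols,
    grid_rows = slide$grid_rows, tiles = slide$tiles,
    foreground = slide$foreground, tissue_detected = slide$tissue_detected)
  saveRDS(state, out, compress = "gzip")
  invisible(out)
}

#' Reload slide state
#'
#' @param path A `.pml` file written by [save_state()].
#' @param level Optional 0-based active level override; defaults to the
#'   level stored in the state.
#' @return The restored `slideforge_slide`, pixels re-read from the source
#'   image recorded in the state.
#' @export
load_state <- function(path, level = NULL) {
  state <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(state) || !identical(state$format, "slideforge-state"))
    sf_stop(sprintf("`%s` is not a slideforge state file", path),
            "slideforge_parse_error")
  slide <- open_slide(state$path, level = state$level)
  for (f in c("tile_size", "tile_overlap", "stride", "grid_cols",
              "grid_rows", "tiles", "foreground", "tissue_detected"))
    slide[[f]] <- state[[f]]
  if (!is.null(level)) slide <- set_active_level(slide, level)
  slide
}

#' Flat (unpyramided) image size
#'
#' Size of a flat raster of the given pixel dimensions and bit depth, in
#' decimal gigabytes. An 80,000 x 80,000 slide at standard 24-bit colour
#' is 19.2 GB -- the reason whole-slide images are stored as pyramids and
#' processed as tiles.
#'
#' @param width,height Pixel dimensions.
#' @param bits_per_pixel Colour depth (default 24-bit RGB).
#' @return Size in decimal GB (1 GB = 1e9 bytes).
#' @examples
#' flat_image_size_gb(80000, 80000) # 19.2
#' @export
flat_image_size_gb <- function(width, height, bits_per_pixel = 24) {
  width * height * bits_per_pixel / 8 / 1e9
}
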