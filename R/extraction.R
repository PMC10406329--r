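# Tile and segmentation-mask extraction to a class-per-directory layout.

#' Channel statistics accumulator
#'
#' Per-colour-channel pixel count, sum and sum of squares on the 0--1
#' scale, accumulated over extracted tiles so that statistics merge across
#' tiles and slides.
#'
#' @param stats,other `slideforge_channel_stats` objects.
#' @param img A tile array to accumulate.
#' @return `new_channel_stats()` and friends return the updated
#'   accumulator; [finalize_channel_stats()] returns a data frame with
#'   per-channel `mean` and `variance`.
#' @export
new_channel_stats <- function() {
  structure(list(count = numeric(3), sum = numeric(3),
                 sum_sq = numeric(3)), class = "slideforge_channel_stats")
}

#' @rdname new_channel_stats
#' @export
update_channel_stats <- function(stats, img) {
  for (ch in 1:3) {
    v <- img[, , ch]
    stats$count[ch] <- stats$count[ch] + length(v)
    stats$sum[ch] <- stats$sum[ch] + sum(v)
    stats$sum_sq[ch] <- stats$sum_sq[ch] + sum(v^2)
  }
  stats
}

#' @rdname new_channel_stats
#' @export
merge_channel_stats <- function(stats, other) {
  stats$count <- stats$count + other$count
  stats$sum <- stats$sum + other$sum
  stats$sum_sq <- stats$sum_sq + other$sum_sq
  stats
}

#' @rdname new_channel_stats
#' @export
finalize_channel_stats <- function(stats) {
  if (any(stats$count == 0))
    sf_stop("Channel statistics are empty: no pixels accumulated",
            "slideforge_validation_error")
  m <- stats$sum / stats$count
  v <- pmax(stats$sum_sq / stats$count - m^2, 0)
  data.frame(channel = c("R", "G", "B"), mean = m, variance = v)
}

resolve_threshold <- function(overlap_threshold, cls) {
  thr <- if (is.list(overlap_threshold) || length(overlap_threshold) > 1) {
    if (is.null(names(overlap_threshold)) || !cls %in% names(overlap_threshold))
      sf_stop(sprintf("No overlap threshold given for class '%s'", cls),
              "slideforge_validation_error")
    overlap_threshold[[cls]]
  } else overlap_threshold
  check_fraction(thr, "overlap_threshold")
}

# Shared eligibility rule: overlap >= class threshold AND tissue filter
# AND foreground filter (all comparisons inclusive).
tile_eligible <- function(rec, cls, overlap_threshold, tissue_threshold,
                          foreground_filter) {
  fr <- if (cls %in% names(rec$overlap)) rec$overlap[[cls]] else 0
  fr >= resolve_threshold(overlap_threshold, cls) &&
    passes_tissue(rec, tissue_threshold) &&
    passes_foreground(rec, foreground_filter)
}

tile_filename <- function(slide, rec, cls, ext = "png") {
  ds <- slide$downsample[slide$level + 1L]
  sprintf("%s_%s_x%d_y%d.%s",
          tools::file_path_sans_ext(basename(slide$path)), cls,
          as.integer(round(rec$x * ds)), as.integer(round(rec$y * ds)), ext)
}

#' Extract class-labelled tiles from annotated regions
#'
#' A tile is eligible for a class when the class's annotations cover at
#' least `overlap_threshold` of its area, and it passes the optional
#' tissue-probability and foreground filters. Per class, up to
#' `num_per_class` eligible tiles are drawn uniformly at random under the
#' given seed and written as PNGs to
#' `output_dir/tiles/<slide>/<class>/`; with `extract_masks`, matching
#' binary masks (0/255 PNGs) go to `output_dir/masks/<slide>/<class>/`.
#' The layout is the image-folder convention (class labels as directory
#' names) that deep-learning dataset loaders consume directly. A tile
#' eligible for several classes is written once per class.
#'
#' @param slide A slide whose tile dictionary has annotation overlaps
#'   (see [annotate_tile_dictionary()]).
#' @param annotations The `slideforge_annotations` used for the overlaps
#'   (needed again when `extract_masks = TRUE`).
#' @param output_dir Output root directory.
#' @param classes_to_extract Character vector of class names.
#' @param overlap_threshold Scalar fraction or named per-class list
#'   (default 0.5).
#' @param num_per_class Maximum tiles per class (default 100). When fewer
#'   are eligible, all are extracted with a warning.
#' @param tissue_threshold Optional minimum tissue probability (the
#'   recommended operating value is 0.995); requires [detect_tissue()].
#' @param foreground_filter Optional `'otsu'`, `'triangle'`, or an
#'   integer 0--100 intensity cut; requires [detect_foreground()].
#' @param extract_masks Also write binary segmentation masks.
#' @param other_class_names Extra class names for which empty directories
#'   are created (so folder datasets see a consistent class set).
#' @param seed Integer seed making the extraction reproducible.
#' @return A `slideforge_channel_stats` accumulated over the written
#'   tiles, with the written file paths in `attr(, "files")`.
#' @export
extract_annotation_tiles <- function(slide, annotations, output_dir,
                                     classes_to_extract,
                                     overlap_threshold = 0.5,
                                     num_per_class = 100L,
                                     tissue_threshold = NULL,
                                     foreground_filter = NULL,
                                     extract_masks = FALSE,
                                     other_class_names = NULL,
                                     seed = 1L) {
  require_tiling(slide)
  num_per_class <- check_count(num_per_class, "num_per_class")
  known <- unique(unlist(lapply(slide$tiles, function(t) names(t$overlap))))
  for (cls in classes_to_extract)
    if (!cls %in% known)
      sf_stop(sprintf("Unknown class '%s': not present in the tile dictionary's annotation overlaps",
                      cls), "slideforge_validation_error")
  slide_name <- tools::file_path_sans_ext(basename(slide$path))
  stats <- new_channel_stats()
  files <- character(0)
  for (cls in c(classes_to_extract, other_class_names)) {
    dir.create(file.path(output_dir, "tiles", slide_name, cls),
               showWarnings = FALSE, recursive = TRUE)
    if (extract_masks)
      dir.create(file.path(output_dir, "masks", slide_name, cls),
                 showWarnings = FALSE, recursive = TRUE)
  }
  for (cls in classes_to_extract) {
    eligible <- which(vapply(slide$tiles, tile_eligible, logical(1), cls,
                             overlap_threshold, tissue_threshold,
                             foreground_filter))
    chosen <- sample_tiles(eligible, num_per_class, seed, cls, "annotation")
    for (k in chosen) {
      rec <- slide$tiles[[k]]
      img <- get_tile(slide, c(rec$col, rec$row))
      fn <- file.path(output_dir, "tiles", slide_name, cls,
                      tile_filename(slide, rec, cls))
      png::writePNG(img, fn)
      files <- c(files, fn)
      stats <- update_channel_stats(stats, img)
      if (extract_masks) {
        mask <- rasterize_tile_mask(slide, c(rec$col, rec$row),
                                    annotations, cls)
        png::writePNG(mask * 1.0,  # {0,1} -> 8-bit {0,255}
                      file.path(output_dir, "masks", slide_name, cls,
                                tile_filename(slide, rec, cls)))
      }
    }
  }
  attr(stats, "files") <- files
  stats
}

# Deterministic per-class sampling with the Table-1-style clamp warning.
sample_tiles <- function(eligible, n_requested, seed, cls, kind) {
  if (length(eligible) == 0) {
    sf_warn(sprintf("0 suitable %s tiles found; nothing extracted for class '%s'",
                    kind, cls), "slideforge_no_tiles")
    return(integer(0))
  }
  if (length(eligible) < n_requested)
    sf_warn(sprintf(
      "%d suitable %s tiles found but requested %d tiles to extract. Extracting all suitable tiles for class '%s'",
      length(eligible), kind, n_requested, cls), "slideforge_clamp")
  with_seed(seed + utils::head(utf8ToInt(cls), 1), {
    sort(sample(eligible, min(n_requested, length(eligible))))
  })
}

#' Extract random tiles from unannotated regions
#'
#' Samples tiles with zero overlap for every annotation class (and passing
#' the optional tissue/foreground filters) and writes them under the given
#' class name — e.g. to harvest plain `tissue` tiles outside any
#' annotation.
#'
#' @inheritParams extract_annotation_tiles
#' @param unannotated_class_name Directory/class name for the sampled
#'   tiles.
#' @param num_tiles Number of tiles to sample.
#' @return A `slideforge_channel_stats` as in
#'   [extract_annotation_tiles()].
#' @export
extract_random_unannotated_tiles <- function(slide, output_dir,
                                             unannotated_class_name,
                                             num_tiles = 100L,
                                             tissue_threshold = NULL,
                                             foreground_filter = NULL,
                                             seed = 1L) {
  require_tiling(slide)
  num_tiles <- check_count(num_tiles, "num_tiles")
  slide_name <- tools::file_path_sans_ext(basename(slide$path))
  eligible <- which(vapply(slide$tiles, function(rec) {
    all(rec$overlap == 0) &&
      passes_tissue(rec, tissue_threshold) &&
      passes_foreground(rec, foreground_filter)
  }, logical(1)))
  dir.create(file.path(output_dir, "tiles", slide_name,
                       unannotated_class_name),
             showWarnings = FALSE, recursive = TRUE)
  chosen <- sample_tiles(eligible, num_tiles, seed, unannotated_class_name,
                         "unannotated")
  stats <- new_channel_stats()
  files <- character(0)
  for (k in chosen) {
    rec <- slide$tiles[[k]]
    img <- get_tile(slide, c(rec$col, rec$row))
    fn <- file.path(output_dir, "tiles", slide_name, unannotated_class_name,
                    tile_filename(slide, rec, unannotated_class_name))
    png::writePNG(img, fn)
    files <- c(files, fn)
    stats <- update_channel_stats(stats, img)
  }
  attr(stats, "files") <- files
  stats
}

#' Rasterize one tile's binary segmentation mask
#'
#' A pixel is foreground exactly when its centre lies inside the class's
#' annotation region (same-class union, doughnut holes excluded).
#'
#' @inheritParams tile_overlap_fraction
#' @return `tile_size` x `tile_size` integer matrix of 0/1.
#' @export
rasterize_tile_mask <- function(slide, address, annotations, class_name) {
  require_tiling(slide)
  a <- resolve_address(slide, address)
  rec <- slide$tiles[[tile_key(a["col"], a["row"])]]
  ts <- slide$tile_size
  region <- annotations$classes[[class_name]]
  mask <- matrix(0L, ts, ts)
  if (is.null(region) || length(region) == 0) return(mask)
  ds <- slide$downsample[slide$level + 1L]
  # pixel-centre coordinates at level 0
  cx <- (rec$x + (seq_len(ts) - 0.5)) * ds
  cy <- (rec$y + (seq_len(ts) - 0.5)) * ds
  px <- rep(cx, each = ts)   # column-major fill: rows vary fastest
  py <- rep(cy, times = ts)
  matrix(as.integer(points_in_region(px, py, region)), ts, ts)
}

#' Extract tiles with stacked multi-class segmentation masks
#'
#' Like [extract_annotation_tiles()] with masks, but instead of one flat
#' binary mask per class, each extracted tile gets a single stacked array
#' of shape `(tile_size, tile_size, n_classes)` — channel order following
#' `classes_to_extract` — saved as a compressed `.rds` beside the tile
#' PNGs, under `output_dir/masks/<slide>/<class>/`.
#'
#' @inheritParams extract_annotation_tiles
#' @return A `slideforge_channel_stats` as in
#'   [extract_annotation_tiles()].
#' @export
extract_multiclass_masks <- function(slide, annotations, output_dir,
                                     classes_to_extract,
                                     overlap_threshold = 0.5,
                                     num_per_class = 100L,
                                     tissue_threshold = NULL,
                                     foreground_filter = NULL,
                                     seed = 1L) {
  require_tiling(slide)
  stats <- extract_annotation_tiles(
    slide, annotations, output_dir, classes_to_extract,
    overlap_threshold = overlap_threshold, num_per_class = num_per_class,
    tissue_threshold = tissue_threshold,
    foreground_filter = foreground_filter,
    extract_masks = FALSE, seed = seed)
  slide_name <- tools::file_path_sans_ext(basename(slide$path))
  ts <- slide$tile_size
  addr <- tile_addresses(slide)
  ds <- slide$downsample[slide$level + 1L]
  for (fn in attr(stats, "files")) {
    cls <- basename(dirname(fn))
    m <- regmatches(basename(fn),
                    regexec("_x([0-9]+)_y([0-9]+)\\.png$", basename(fn)))[[1]]
    x <- as.integer(m[2]) / ds; y <- as.integer(m[3]) / ds
    k <- which(addr$x == x & addr$y == y)[1]
    stack <- array(0L, dim = c(ts, ts, length(classes_to_extract)))
    for (ci in seq_along(classes_to_extract))
      stack[, , ci] <- rasterize_tile_mask(
        slide, c(addr$col[k], addr$row[k]), annotations,
        classes_to_extract[ci])
    dir.create(file.path(output_dir, "masks", slide_name, cls),
               showWarnings = FALSE, recursive = TRUE)
    saveRDS(stack, file.path(output_dir, "masks", slide_name, cls,
                             sub("\\.png$", ".rds", basename(fn))),
            compress = "gzip")
  }
  stats
}
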