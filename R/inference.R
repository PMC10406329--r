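# Tile-level inference bookkeeping, visualization, and stitching of
# overlapping segmentation predictions into a slide-level array.

infer_passing_tiles <- function(slide, tissue_threshold, foreground_filter) {
  which(vapply(slide$tiles, function(rec)
    passes_tissue(rec, tissue_threshold) &&
      passes_foreground(rec, foreground_filter), logical(1)))
}

check_class_names <- function(model, class_names) {
  if (model$class_count != length(class_names))
    sf_stop(sprintf(
      "Model has %d classes but only %d class names were provided in the class_names argument",
      model$class_count, length(class_names)),
      "slideforge_class_mismatch")
  invisible(class_names)
}

#' Run a tile classifier over the filtered tile grid
#'
#' Every tile passing the optional tissue-probability and foreground
#' filters receives a named probability vector over `class_names`;
#' non-passing tiles are left without a prediction.
#'
#' @param slide A slide with tile properties set.
#' @param model A classifier `slideforge_model`.
#' @param class_names Ordered class names; length must equal the model's
#'   class count.
#' @param tissue_threshold Optional minimum tissue probability (requires
#'   [detect_tissue()]).
#' @param foreground_filter Optional `'otsu'`/`'triangle'`/integer cut
#'   (requires [detect_foreground()]).
#' @param batch_size Tiles per model call.
#' @return The slide with `classifier_probs` filled on passing tiles.
#' @export
infer_classifier <- function(slide, model, class_names,
                             tissue_threshold = NULL,
                             foreground_filter = NULL, batch_size = 32L) {
  require_tiling(slide)
  check_class_names(model, class_names)
  idx <- infer_passing_tiles(slide, tissue_threshold, foreground_filter)
  for (b in seq_len(ceiling(length(idx) / batch_size))) {
    take <- idx[((b - 1L) * batch_size + 1L):min(b * batch_size, length(idx))]
    tiles <- lapply(take, function(k) {
      rec <- slide$tiles[[k]]
      get_tile(slide, c(rec$col, rec$row))
    })
    p <- predict(model, tiles)
    for (j in seq_along(take)) {
      v <- p[j, ]
      names(v) <- class_names
      slide$tiles[[take[j]]]$classifier_probs <- v
    }
  }
  slide
}

#' Run a tile segmenter over the filtered tile grid
#'
#' As [infer_classifier()], but the model returns per-pixel probability
#' maps: one `tile_size x tile_size x n_classes` array per tile, values
#' in `[0, 1]`, channel order following `class_names`.
#'
#' @inheritParams infer_classifier
#' @param model A segmenter `slideforge_model`.
#' @return The slide with `segmenter_probs` filled on passing tiles.
#' @export
infer_segmenter <- function(slide, model, class_names,
                            tissue_threshold = NULL,
                            foreground_filter = NULL, batch_size = 32L) {
  require_tiling(slide)
  check_class_names(model, class_names)
  ts <- slide$tile_size
  idx <- infer_passing_tiles(slide, tissue_threshold, foreground_filter)
  for (b in seq_len(ceiling(length(idx) / batch_size))) {
    take <- idx[((b - 1L) * batch_size + 1L):min(b * batch_size, length(idx))]
    tiles <- lapply(take, function(k) {
      rec <- slide$tiles[[k]]
      get_tile(slide, c(rec$col, rec$row))
    })
    maps <- predict(model, tiles)
    for (j in seq_along(take)) {
      m <- maps[[j]]
      if (!identical(dim(m)[1:2], c(ts, ts)) ||
          dim(m)[3] != length(class_names) ||
          any(m < 0 | m > 1))
        sf_stop("Segmenter output must be tile_size x tile_size x n_classes probabilities in [0, 1]",
                "slideforge_model_error")
      dimnames(m) <- list(NULL, NULL, class_names)
      slide$tiles[[take[j]]]$segmenter_probs <- m
    }
  }
  slide
}

no_predictions_stop <- function() {
  sf_stop("No predictions found in slide. Use infer_classifier() / infer_segmenter() to generate them",
          "slideforge_no_predictions")
}

#' Visualize tile-level inference
#'
#' Writes a PNG of the chosen pyramid level's thumbnail with each inferred
#' tile tinted red in proportion to its predicted probability for one
#' class. `visualize_classifier_inference()` uses the per-tile class
#' probability; `visualize_segmenter_inference()` the mean of the tile's
#' probability map for the class.
#'
#' @param slide A slide after inference.
#' @param class_to_visualize Class name.
#' @param level 0-based pyramid level of the backdrop thumbnail.
#' @param folder Output directory.
#' @param filename Output file name.
#' @return Path of the written PNG, invisibly.
#' @export
visualize_classifier_inference <- function(slide, class_to_visualize,
                                           level = nrow(slide$levels) - 1L,
                                           folder,
                                           filename = "classifier_inference.png") {
  write_inference_overlay(slide, class_to_visualize, level, folder, filename,
                          kind = "classifier_probs")
}

#' @rdname visualize_classifier_inference
#' @export
visualize_segmenter_inference <- function(slide, class_to_visualize,
                                          level = nrow(slide$levels) - 1L,
                                          folder,
                                          filename = "segmenter_inference.png") {
  write_inference_overlay(slide, class_to_visualize, level, folder, filename,
                          kind = "segmenter_probs")
}

write_inference_overlay <- function(slide, cls, level, folder, filename,
                                    kind) {
  require_tiling(slide)
  has <- vapply(slide$tiles, function(t) !is.null(t[[kind]]), logical(1))
  if (!any(has)) no_predictions_stop()
  thumb <- level_image(slide, level)
  for (rec in slide$tiles[has]) {
    p <- if (kind == "classifier_probs") rec$classifier_probs[[cls]]
         else mean(rec$segmenter_probs[, , cls])
    tr <- tile_thumb_rect(slide, rec, level)
    a <- 0.6 * p
    thumb[tr$rows, tr$cols, 1] <- (1 - a) * thumb[tr$rows, tr$cols, 1] + a
    thumb[tr$rows, tr$cols, 2] <- (1 - a) * thumb[tr$rows, tr$cols, 2]
    thumb[tr$rows, tr$cols, 3] <- (1 - a) * thumb[tr$rows, tr$cols, 3]
  }
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(folder, filename)
  png::writePNG(thumb, out)
  invisible(out)
}

#' Stitch overlapping tile segmentations into a slide-level array
#'
#' Merges the per-tile segmentation probability maps for one class into a
#' single array at the inference level. Where tiles overlap, the merged
#' probability of a pixel is the arithmetic mean of all contributing tile
#' predictions (`merge = "max"` takes their maximum instead). Pixels
#' outside every tile are 0, distinguishable from true zero predictions
#' via the `coverage` plane (per-pixel count of contributing tiles).
#'
#' With a `probability_threshold`, the result is a logical array (merged
#' probability at or above the threshold). Otherwise `dtype = "int"` maps
#' probabilities to unsigned-8-bit style integers 0--255 (255 is 100%
#' probability, round-half-up) and `dtype = "float"` keeps the raw means.
#'
#' @param slide A slide after [infer_segmenter()].
#' @param class_name Class whose predictions to stitch.
#' @param probability_threshold Optional fraction in `[0, 1]`.
#' @param dtype `"int"` (default) or `"float"`.
#' @param merge `"mean"` (default) or `"max"`.
#' @param folder Optional directory; when given, the result is saved as a
#'   compressed `.rds` holding `values` and `coverage`.
#' @return Object of class `slideforge_stitched`: list with `values`
#'   (matrix, level dimensions), `coverage`, `class_name`, `dtype`.
#' @export
stitch_segmentation <- function(slide, class_name,
                                probability_threshold = NULL,
                                dtype = c("int", "float"),
                                merge = c("mean", "max"), folder = NULL) {
  require_tiling(slide)
  dtype <- match.arg(dtype)
  merge <- match.arg(merge)
  if (!is.null(probability_threshold))
    check_fraction(probability_threshold, "probability_threshold")
  has <- vapply(slide$tiles, function(t)
    !is.null(t$segmenter_probs) &&
      class_name %in% dimnames(t$segmenter_probs)[[3]], logical(1))
  if (!any(has)) no_predictions_stop()
  w <- slide$levels$width[slide$level + 1L]
  h <- slide$levels$height[slide$level + 1L]
  acc <- matrix(0, h, w)
  coverage <- matrix(0L, h, w)
  ts <- slide$tile_size
  for (rec in slide$tiles[has]) {
    rows <- rec$y + seq_len(ts); cols <- rec$x + seq_len(ts)
    m <- rec$segmenter_probs[, , class_name]
    if (merge == "mean") acc[rows, cols] <- acc[rows, cols] + m
    else acc[rows, cols] <- pmax(acc[rows, cols], m)
    coverage[rows, cols] <- coverage[rows, cols] + 1L
  }
  merged <- if (merge == "mean")
    ifelse(coverage > 0, acc / pmax(coverage, 1L), 0) else acc
  values <- if (!is.null(probability_threshold)) {
    merged >= probability_threshold & coverage > 0
  } else if (dtype == "int") {
    matrix(as.integer(floor(merged * 255 + 0.5)), h, w)
  } else merged
  out <- structure(list(values = values, coverage = coverage,
                        class_name = class_name, dtype = dtype,
                        merge = merge,
                        threshold = probability_threshold),
                   class = "slideforge_stitched")
  if (!is.null(folder)) {
    dir.create(folder, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(folder, sprintf(
      "%s_%s_stitched.rds",
      tools::file_path_sans_ext(basename(slide$path)), class_name))
    saveRDS(out, path, compress = "gzip")
    attr(out, "path") <- path
  }
  out
}

#' @export
print.slideforge_stitched <- function(x, ...) {
  cat(sprintf("<slideforge_stitched> class '%s', %d x %d, %s, max coverage %d\n",
              x$class_name, nrow(x$values), ncol(x$values),
              if (!is.null(x$threshold))
                sprintf("binary at %.3g", x$threshold) else x$dtype,
              max(x$coverage)))
  invisible(x)
}
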