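# Tile models and the 3-class (artefact/background/tissue) tissue detector.

TISSUE_CLASSES <- c("artefact", "background", "tissue")

#' Construct a tile model
#'
#' Wraps an arbitrary prediction function in the tile-model contract used
#' throughout the package, so externally trained models plug in with no
#' other behavioural change.
#'
#' @param predict_fn For a classifier: function taking a list of tile
#'   arrays (`h x w x 3`, values in `[0, 1]`) and returning an
#'   `n x class_count` matrix of probabilities (rows summing to 1). For a
#'   segmenter: function returning a list of `h x w x class_count` arrays
#'   of per-pixel probabilities in `[0, 1]`.
#' @param class_count Number of output classes.
#' @param type `"classifier"` or `"segmenter"`.
#' @param name Optional label for printing.
#' @return Object of class `slideforge_model`.
#' @export
tile_model <- function(predict_fn, class_count,
                       type = c("classifier", "segmenter"),
                       name = "custom") {
  stopifnot(is.function(predict_fn))
  structure(list(predict_fn = predict_fn,
                 class_count = check_count(class_count, "class_count"),
                 type = match.arg(type), name = name),
            class = "slideforge_model")
}

#' @export
print.slideforge_model <- function(x, ...) {
  cat(sprintf("<slideforge_model> %s (%s, %d classes)\n",
              x$name, x$type, x$class_count))
  invisible(x)
}

#' @param object A `slideforge_model`.
#' @param tiles List of tile arrays.
#' @param ... Unused.
#' @rdname tile_model
#' @export
predict.slideforge_model <- function(object, tiles, ...) {
  out <- object$predict_fn(tiles)
  if (object$type == "classifier") {
    out <- matrix(as.numeric(out), nrow = length(tiles))
    if (ncol(out) != object$class_count ||
        any(abs(rowSums(out) - 1) > 1e-6))
      sf_stop("Classifier model output must be n x class_count probabilities summing to 1",
              "slideforge_model_error")
  }
  out
}

#' Constant-output tile model (useful for plumbing tests)
#' @param probs Probability vector returned for every tile.
#' @return A classifier `slideforge_model`.
#' @export
constant_model <- function(probs) {
  probs <- probs / sum(probs)
  k <- length(probs)
  tile_model(function(tiles)
    matrix(rep(probs, each = length(tiles)), nrow = length(tiles)),
    class_count = k, name = "constant")
}

# Per-tile colour summary features: channel means and sds plus grey mean.
tile_features <- function(tiles) {
  t(vapply(tiles, function(img) {
    m <- apply(img, 3, mean)
    s <- apply(img, 3, stats::sd)
    c(m, s, mean(rgb_to_grey255(img)) / 255)
  }, numeric(7)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a small tissue-detector on labelled fixture tiles
#'
#' Fits a multinomial softmax classifier on per-tile colour summary
#' features (channel means/sds and grey level) by minibatch gradient
#' descent with class-balanced sampling: every draw first picks a class
#' uniformly, then a tile uniformly within that class, so each class is
#' seen with equal expected frequency per epoch regardless of class sizes.
#' The per-epoch draw counts are kept on the returned model
#' (`attr(model, "sampling_log")`) so balance can be audited. Deterministic
#' under a fixed seed.
#'
#' @param tiles List of tile arrays (`h x w x 3`, values in `[0, 1]`).
#' @param labels Character vector of class labels, one per tile.
#' @param seed Integer RNG seed.
#' @param epochs Training epochs; one epoch makes `length(tiles)` draws.
#' @param learning_rate Gradient step size.
#' @param batch_size Minibatch size.
#' @return A classifier `slideforge_model` whose classes are
#'   `sort(unique(labels))` (for the tissue detector: artefact,
#'   background, tissue — already alphabetical).
#' @export
train_fixture_detector <- function(tiles, labels, seed = 1L, epochs = 20L,
                                   learning_rate = 0.5, batch_size = 32L) {
  stopifnot(length(tiles) == length(labels))
  classes <- sort(unique(labels))
  k <- length(classes)
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  n_by_class <- lengths(idx_by_class)
  if (any(n_by_class == 0) || k < 2)
    sf_stop("Every class needs at least one tile (and at least 2 classes)",
            "slideforge_validation_error")
  feats <- tile_features(tiles)
  mu <- colMeans(feats)
  sdv <- pmax(apply(feats, 2, stats::sd), 1e-8)
  X <- cbind(1, sweep(sweep(feats, 2, mu), 2, sdv, "/"))
  Y <- outer(labels, classes, "==") * 1
  W <- matrix(0, ncol(X), k)
  draws_per_epoch <- length(tiles)
  log_mat <- matrix(0L, nrow = epochs, ncol = k,
                    dimnames = list(NULL, classes))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      drawn_class <- sample.int(k, draws_per_epoch, replace = TRUE)
      drawn_idx <- vapply(drawn_class, function(ci) {
        pool <- idx_by_class[[ci]]
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      log_mat[ep, ] <- tabulate(drawn_class, nbins = k)
      for (b in seq(1, draws_per_epoch, by = batch_size)) {
        take <- drawn_idx[b:min(b + batch_size - 1L, draws_per_epoch)]
        P <- softmax_rows(X[take, , drop = FALSE] %*% W)
        grad <- crossprod(X[take, , drop = FALSE],
                          P - Y[take, , drop = FALSE]) / length(take)
        W <- W - learning_rate * grad
      }
    }
  })
  predict_fn <- local({
    W <- W; mu <- mu; sdv <- sdv
    function(tiles) {
      f <- tile_features(tiles)
      softmax_rows(cbind(1, sweep(sweep(f, 2, mu), 2, sdv, "/")) %*% W)
    }
  })
  model <- tile_model(predict_fn, class_count = k, name = "fixture-detector")
  attr(model, "classes") <- classes
  attr(model, "sampling_log") <- log_mat
  model
}

#' Apply the tissue detector over a slide
#'
#' Runs a 3-class (artefact, background, tissue) tile classifier on its
#' own detection grid at a chosen pyramid level and carries the
#' probabilities over to the working tile grid: each working tile receives
#' the probability vector of the detection tile containing its centre
#' (coordinates mapped through the downsample ratio; centres over a
#' dropped detection-grid edge clamp to the nearest detection tile).
#'
#' @param slide A slide with tile properties set.
#' @param model A classifier `slideforge_model` with exactly 3 classes, in
#'   (artefact, background, tissue) order — e.g. from
#'   [train_fixture_detector()] on tiles labelled with those names, or any
#'   externally trained model wrapped with [tile_model()].
#' @param detection_level 0-based pyramid level the detector runs on.
#' @param detection_tile_size Detection tile side in pixels at that level.
#' @param detection_overlap Fractional overlap of the detection grid.
#' @param upsample_factor Nearest-neighbour upsampling factor applied to
#'   the detection probability map before centre lookup (>= 1; with centre
#'   lookup this refines rounding only).
#' @param batch_size Tiles per model call.
#' @param overwrite Set `TRUE` to allow re-running detection.
#' @return The slide with `tissue_probs` (named artefact/background/
#'   tissue, summing to 1) on every working tile.
#' @export
detect_tissue <- function(slide, model,
                          detection_level = min(1L, nrow(slide$levels) - 1L),
                          detection_tile_size = 512L,
                          detection_overlap = 0,
                          upsample_factor = 1L,
                          batch_size = 32L,
                          overwrite = FALSE) {
  require_tiling(slide)
  if (slide$tissue_detected && !overwrite)
    sf_stop("Tissue detection has already been performed. Use overwrite = TRUE if you wish to write over it",
            "slideforge_already_detected")
  if (model$class_count != 3L)
    sf_stop(sprintf(
      "Model has %d classes but the tissue detector requires exactly 3 (artefact, background, tissue)",
      model$class_count), "slideforge_class_mismatch")
  check_count(upsample_factor, "upsample_factor", min = 1L)
  det <- set_active_level(slide, detection_level)
  dw <- slide$levels$width[detection_level + 1L]
  dh <- slide$levels$height[detection_level + 1L]
  detection_tile_size <- min(as.integer(detection_tile_size), dw, dh)
  g <- tile_grid_dims(dw, dh, detection_tile_size, detection_overlap)
  img <- level_image(slide, detection_level)
  addrs <- expand.grid(col = seq_len(g$cols) - 1L, row = seq_len(g$rows) - 1L)
  probs <- matrix(NA_real_, nrow(addrs), 3)
  for (b in seq(1, nrow(addrs), by = batch_size)) {
    take <- b:min(b + batch_size - 1L, nrow(addrs))
    batch <- lapply(take, function(i) {
      x <- addrs$col[i] * g$stride; y <- addrs$row[i] * g$stride
      img[y + seq_len(detection_tile_size), x + seq_len(detection_tile_size),
          , drop = FALSE]
    })
    probs[take, ] <- predict(model, batch)
  }
  # working-tile centre -> detection-level coords -> containing tile
  ratio <- slide$downsample[detection_level + 1L] /
    slide$downsample[slide$level + 1L]
  for (k in seq_along(slide$tiles)) {
    t <- slide$tiles[[k]]
    cx <- (t$x + slide$tile_size / 2) / ratio
    cy <- (t$y + slide$tile_size / 2) / ratio
    col <- min(max(as.integer(cx %/% g$stride), 0L), g$cols - 1L)
    row <- min(max(as.integer(cy %/% g$stride), 0L), g$rows - 1L)
    p <- probs[row * g$cols + col + 1L, ]
    names(p) <- TISSUE_CLASSES
    slide$tiles[[k]]$tissue_probs <- p
  }
  slide$tissue_detected <- TRUE
  slide
}

# Does a record pass the tissue-probability filter?
passes_tissue <- function(rec, tissue_threshold) {
  if (is.null(tissue_threshold)) return(TRUE)
  if (is.null(rec$tissue_probs))
    sf_stop("No tissue predictions found in slide. Use detect_tissue() to generate them",
            "slideforge_state_error")
  rec$tissue_probs[["tissue"]] >= tissue_threshold
}

# Scale a tile rectangle (active level) onto thumbnail pixel indices.
tile_thumb_rect <- function(slide, rec, thumb_level) {
  r <- slide$downsample[thumb_level + 1L] / slide$downsample[slide$level + 1L]
  th <- slide$levels$height[thumb_level + 1L]
  tw <- slide$levels$width[thumb_level + 1L]
  list(rows = max(1L, floor(rec$y / r) + 1L):
         min(th, ceiling((rec$y + slide$tile_size) / r)),
       cols = max(1L, floor(rec$x / r) + 1L):
         min(tw, ceiling((rec$x + slide$tile_size) / r)))
}

#' Visualize tissue-detector output
#'
#' Writes a PNG of the lowest-resolution slide thumbnail with each working
#' tile tinted by its argmax tissue-detector class: artefact red,
#' background blue, tissue green.
#'
#' @param slide A slide after [detect_tissue()].
#' @param folder Output directory.
#' @param filename Output file name.
#' @return Path of the written PNG, invisibly.
#' @export
visualize_tissue_detection <- function(slide, folder,
                                       filename = "tissue_detection.png") {
  require_tiling(slide)
  if (!slide$tissue_detected)
    sf_stop("No tissue predictions found in slide. Use detect_tissue() to generate them",
            "slideforge_state_error")
  thumb_level <- nrow(slide$levels) - 1L
  thumb <- level_image(slide, thumb_level)
  tint <- list(artefact = c(1, 0, 0), background = c(0, 0, 1),
               tissue = c(0, 1, 0))
  alpha <- 0.45
  for (rec in slide$tiles) {
    cls <- TISSUE_CLASSES[which.max(rec$tissue_probs)]
    tr <- tile_thumb_rect(slide, rec, thumb_level)
    for (ch in 1:3)
      thumb[tr$rows, tr$cols, ch] <-
        (1 - alpha) * thumb[tr$rows, tr$cols, ch] + alpha * tint[[cls]][ch]
  }
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(folder, filename)
  png::writePNG(thumb, out)
  invisible(out)
}
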