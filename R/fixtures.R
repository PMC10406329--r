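# Synthetic pyramidal slides with ground truth: white background, coloured
# "tissue" blobs and pen-mark-like "artefact" regions, a factor-2 pyramid,
# and matching annotation files, so the whole pipeline is testable without
# slide downloads.

#' Default fixture palette
#'
#' Region colours are picked far apart in RGB (and far from the white
#' background) so that fixture tiles are colour-separable: tissue is a
#' stain-like purple, artefacts a pen-mark blue.
#' @return Named list of RGB triples in `[0, 1]`.
#' @export
fixture_palette <- function() {
  list(tissue = c(128, 0, 128) / 255,
       artefact = c(0, 0, 255) / 255,
       background = c(1, 1, 1))
}

#' Region constructors for synthetic slides
#'
#' @param region_class `"tissue"` or `"artefact"`.
#' @param cx,cy Centre in level-0 pixels.
#' @param r Disc radius in pixels.
#' @param x0,y0,x1,y1 Rectangle corners (half-open) in level-0 pixels.
#' @param x,y Polygon vertex coordinates in level-0 pixels.
#' @param colour RGB triple in `[0, 1]`; defaults to the palette colour of
#'   `region_class`.
#' @return A region description for [synthetic_slide_spec()].
#' @export
region_disc <- function(region_class, cx, cy, r, colour = NULL) {
  list(shape = "disc", class = region_class, cx = cx, cy = cy, r = r,
       colour = colour %||% fixture_palette()[[region_class]])
}

#' @rdname region_disc
#' @export
region_rect <- function(region_class, x0, y0, x1, y1, colour = NULL) {
  list(shape = "rect", class = region_class, x0 = x0, y0 = y0, x1 = x1,
       y1 = y1, colour = colour %||% fixture_palette()[[region_class]])
}

#' @rdname region_disc
#' @export
region_polygon <- function(region_class, x, y, colour = NULL) {
  list(shape = "polygon", class = region_class, x = x, y = y,
       colour = colour %||% fixture_palette()[[region_class]])
}

#' Specify a synthetic pyramidal slide
#'
#' @param width,height Level-0 dimensions in pixels.
#' @param n_levels Number of pyramid levels (factor-2, floor halving).
#' @param regions List of regions from [region_disc()] and friends,
#'   painted in order onto a white background.
#' @param noise_sd Gaussian pixel noise standard deviation on the `[0, 1]`
#'   scale (default 0.02, about 5 grey levels — visible texture that
#'   leaves the fixture colours trivially separable).
#' @param seed Integer seed; generation is byte-reproducible under it.
#' @return A `slideforge_slide_spec`.
#' @export
synthetic_slide_spec <- function(width, height, n_levels = 3L,
                                 regions = list(), noise_sd = 0.02,
                                 seed = 1L) {
  width <- check_count(width, "width"); height <- check_count(height, "height")
  n_levels <- check_count(n_levels, "n_levels")
  for (rg in regions) {
    bb <- region_bbox(rg)
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > width || bb[4] > height)
      sf_stop(sprintf("A %s region of class '%s' extends outside the %d x %d slide",
                      rg$shape, rg$class, width, height),
              "slideforge_validation_error")
  }
  structure(list(width = width, height = height, n_levels = n_levels,
                 regions = regions, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "slideforge_slide_spec")
}

region_bbox <- function(rg) {
  switch(rg$shape,
         disc = c(rg$cx - rg$r, rg$cy - rg$r, rg$cx + rg$r, rg$cy + rg$r),
         rect = c(rg$x0, rg$y0, rg$x1, rg$y1),
         polygon = c(min(rg$x), min(rg$y), max(rg$x), max(rg$y)))
}

region_ring <- function(rg, n_disc_vertices = 72L) {
  switch(rg$shape,
         disc = {
           th <- 2 * pi * (seq_len(n_disc_vertices) - 1L) / n_disc_vertices
           list(x = rg$cx + rg$r * cos(th), y = rg$cy + rg$r * sin(th))
         },
         rect = rect_ring(rg$x0, rg$y0, rg$x1, rg$y1),
         polygon = list(x = rg$x, y = rg$y))
}

# Logical mask of pixel centres inside a region, on the level-0 grid.
region_pixel_mask <- function(rg, width, height) {
  cx <- seq_len(width) - 0.5
  cy <- seq_len(height) - 0.5
  if (rg$shape == "disc") {
    outer((cy - rg$cy)^2, (cx - rg$cx)^2, "+") <= rg$r^2
  } else {
    ring <- region_ring(rg)
    px <- rep(cx, each = height)
    py <- rep(cy, times = width)
    matrix(points_in_region(px, py, list(ring)), height, width)
  }
}

#' Generate a synthetic pyramidal slide
#'
#' Paints the spec's regions onto a white level-0 canvas, adds seeded
#' Gaussian noise, builds the factor-2 pyramid by 2x2 mean pooling, and
#' writes everything as a multi-page 8-bit TIFF. Deterministic: the same
#' spec produces a byte-identical file.
#'
#' @param spec A `slideforge_slide_spec`.
#' @param path Output TIFF path.
#' @return Invisibly, a `slideforge_truth`: `labels` (level-0 integer
#'   matrix: 0 background, 1 tissue, 2 artefact), `class_polygons`
#'   (level-0 rings per class), `spec`, and `path`.
#' @export
generate_slide <- function(spec, path) {
  stopifnot(inherits(spec, "slideforge_slide_spec"))
  w <- spec$width; h <- spec$height
  img <- array(1, dim = c(h, w, 3))
  labels <- matrix(0L, h, w)
  class_code <- c(background = 0L, tissue = 1L, artefact = 2L)
  polys <- list()
  for (rg in spec$regions) {
    m <- region_pixel_mask(rg, w, h)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- rg$colour[ch]
      img[, , ch] <- plane
    }
    labels[m] <- class_code[[rg$class]]
    polys[[rg$class]] <- c(polys[[rg$class]], list(region_ring(rg)))
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                                 dim = dim(img)))
    img <- pmin(pmax(img, 0), 1)
  }
  pages <- list(quantize_uint8(img))
  for (l in seq_len(spec$n_levels - 1L))
    pages[[l + 1L]] <- quantize_uint8(mean_pool2(pages[[l]]))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  invisible(structure(list(labels = labels, class_polygons = polys,
                           spec = spec, path = path),
                      class = "slideforge_truth"))
}

#' Write ground-truth annotations to a parseable file
#'
#' Serializes the ground-truth class polygons of a synthetic slide as a
#' QuPath-style GeoJSON FeatureCollection or an ASAP XML file, optionally
#' inserting a doughnut-hole annotation (a rectangle centred in the first
#' polygon's bounding box, a quarter of its linear size) to exercise hole
#' subtraction.
#'
#' @param truth A `slideforge_truth` from [generate_slide()].
#' @param format `"geojson"` or `"asap_xml"`.
#' @param path Output file path.
#' @param include_hole Insert the doughnut-hole annotation.
#' @param hole_class Class name of the hole annotation.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(truth, format = c("geojson", "asap_xml"),
                              path, include_hole = FALSE,
                              hole_class = "doughnut_holes") {
  format <- match.arg(format)
  polys <- truth$class_polygons
  if (length(polys) == 0)
    sf_stop("The ground truth has no class polygons to write",
            "slideforge_validation_error")
  entries <- list()
  for (cls in names(polys))
    for (ring in polys[[cls]])
      entries[[length(entries) + 1L]] <- list(class_name = cls, ring = ring)
  if (include_hole) {
    r0 <- entries[[1L]]$ring
    cx <- (min(r0$x) + max(r0$x)) / 2; cy <- (min(r0$y) + max(r0$y)) / 2
    hw <- (max(r0$x) - min(r0$x)) / 8; hh <- (max(r0$y) - min(r0$y)) / 8
    entries[[length(entries) + 1L]] <- list(
      class_name = hole_class,
      ring = rect_ring(cx - hw, cy - hh, cx + hw, cy + hh))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "geojson") {
    feats <- lapply(entries, function(e) {
      coords <- lapply(c(seq_along(e$ring$x), 1L), function(i)
        c(e$ring$x[i], e$ring$y[i]))  # closed ring
      list(type = "Feature",
           properties = list(objectType = "annotation",
                             classification = list(name = e$class_name)),
           geometry = list(type = "Polygon", coordinates = list(coords)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("ASAP_Annotations")
    anns <- xml2::xml_add_child(doc, "Annotations")
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      ann <- xml2::xml_add_child(anns, "Annotation",
                                 Name = sprintf("Annotation %d", i - 1L),
                                 Type = "Polygon",
                                 PartOfGroup = e$class_name,
                                 Color = "#F4FA58")
      coords <- xml2::xml_add_child(ann, "Coordinates")
      for (j in seq_along(e$ring$x))
        xml2::xml_add_child(coords, "Coordinate", Order = as.character(j - 1L),
                            X = format(e$ring$x[j], scientific = FALSE),
                            Y = format(e$ring$y[j], scientific = FALSE))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

# Nearest-reference-colour label per pixel of a tile: 1 artefact,
# 2 background, 3 tissue (alphabetical, matching TISSUE_CLASSES).
nearest_colour_labels <- function(img, palette = fixture_palette()) {
  refs <- rbind(palette$artefact, palette$background, palette$tissue)
  n <- prod(dim(img)[1:2])
  flat <- matrix(img, n, 3)
  d <- vapply(1:3, function(k)
    rowSums(sweep(flat, 2, refs[k, ])^2), numeric(n))
  max.col(-d, ties.method = "first")
}

#' Ground-truth oracle models for pipeline tests
#'
#' Deterministic tile models that recover the synthetic ground truth from
#' tile pixels by nearest-reference-colour matching: the classifier
#' returns each tile's (artefact, background, tissue) pixel fractions as
#' class probabilities; the segmenter returns a 0/1 probability map per
#' requested class. They close the loop for end-to-end tests — a perfect
#' model should score perfectly against the annotations derived from the
#' same ground truth.
#'
#' @param segmenter_classes Class names (and channel order) of the
#'   segmenter's output maps; `"tissue"` and/or `"artefact"`.
#' @param palette Reference colours, as [fixture_palette()].
#' @return List with classifier and segmenter `slideforge_model`s.
#' @export
make_oracle_models <- function(segmenter_classes = "tissue",
                               palette = fixture_palette()) {
  classifier <- tile_model(function(tiles) {
    t(vapply(tiles, function(img) {
      lab <- nearest_colour_labels(img, palette)
      tabulate(lab, nbins = 3) / length(lab)
    }, numeric(3)))
  }, class_count = 3, name = "oracle-classifier")
  code <- c(artefact = 1L, background = 2L, tissue = 3L)
  segmenter <- tile_model(function(tiles) {
    lapply(tiles, function(img) {
      lab <- nearest_colour_labels(img, palette)
      h <- dim(img)[1]; w <- dim(img)[2]
      out <- array(0, dim = c(h, w, length(segmenter_classes)))
      for (ci in seq_along(segmenter_classes))
        out[, , ci] <- matrix(as.numeric(lab == code[[segmenter_classes[ci]]]),
                              h, w)
      out
    })
  }, class_count = length(segmenter_classes), type = "segmenter",
  name = "oracle-segmenter")
  list(classifier = classifier, segmenter = segmenter)
}
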