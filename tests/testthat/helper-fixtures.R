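# Shared synthetic fixtures, built once per test run.

fx_cache <- new.env(parent = emptyenv())

# Standard fixture: 768x512 3-level slide, purple tissue disc, blue
# artefact rectangle, annotations in both formats.
fixture_bundle <- function() {
  if (!is.null(fx_cache$bundle)) return(fx_cache$bundle)
  dir <- file.path(tempdir(), "slideforge-fixture")
  dir.create(dir, showWarnings = FALSE)
  spec <- synthetic_slide_spec(
    768, 512, n_levels = 3,
    regions = list(
      region_disc("tissue", cx = 230, cy = 256, r = 120),
      region_rect("artefact", x0 = 520, y0 = 80, x1 = 660, y1 = 220)),
    seed = 7)
  truth <- generate_slide(spec, file.path(dir, "fixture.tiff"))
  geojson <- file.path(dir, "fixture.geojson")
  xml <- file.path(dir, "fixture.xml")
  write_annotations(truth, "geojson", geojson)
  write_annotations(truth, "asap_xml", xml)
  slide <- set_tile_properties(open_slide(truth$path, level = 0), 64)
  ann <- build_annotation_set(parse_geojson(geojson))
  fx_cache$bundle <- list(dir = dir, spec = spec, truth = truth,
                          slide = slide, annotations = ann,
                          geojson = geojson, xml = xml)
  fx_cache$bundle
}

# Noise-free slide with integer-aligned rectangles only: geometry and
# pixels agree exactly, so equality assertions can be sharp.
aligned_bundle <- function() {
  if (!is.null(fx_cache$aligned)) return(fx_cache$aligned)
  dir <- file.path(tempdir(), "slideforge-aligned")
  dir.create(dir, showWarnings = FALSE)
  spec <- synthetic_slide_spec(
    256, 128, n_levels = 2,
    regions = list(
      region_rect("tissue", x0 = 0, y0 = 0, x1 = 128, y1 = 64),
      region_rect("artefact", x0 = 192, y0 = 64, x1 = 256, y1 = 128)),
    noise_sd = 0, seed = 1)
  truth <- generate_slide(spec, file.path(dir, "aligned.tiff"))
  slide <- set_tile_properties(open_slide(truth$path, level = 0), 64)
  ann <- build_annotation_set(list(
    list(class_name = "tissue", x = c(0, 128, 128, 0), y = c(0, 0, 64, 64)),
    list(class_name = "artefact", x = c(192, 256, 256, 192),
         y = c(64, 64, 128, 128))))
  fx_cache$aligned <- list(dir = dir, truth = truth, slide = slide,
                           annotations = ann)
  fx_cache$aligned
}

# Labelled training tiles cropped from the standard fixture, one label
# per ground-truth region of the crop centre.
fixture_training_tiles <- function(n_per_class = 60, tile_px = 32,
                                   seed = 11) {
  fx <- fixture_bundle()
  img0 <- slideforge:::level_image(fx$slide, 0)
  labels_map <- fx$truth$labels
  class_of <- c("background", "tissue", "artefact")
  tiles <- list(); labels <- character(0)
  set.seed(seed)
  need <- c(background = n_per_class, tissue = n_per_class,
            artefact = n_per_class)
  guard <- 0
  while (any(need > 0) && guard < 50000) {
    guard <- guard + 1
    x <- sample(0:(768 - tile_px), 1); y <- sample(0:(512 - tile_px), 1)
    lab <- class_of[labels_map[y + tile_px / 2, x + tile_px / 2] + 1L]
    if (need[[lab]] > 0) {
      tiles[[length(tiles) + 1L]] <-
        img0[y + seq_len(tile_px), x + seq_len(tile_px), , drop = FALSE]
      labels <- c(labels, lab)
      need[[lab]] <- need[[lab]] - 1L
    }
  }
  list(tiles = tiles, labels = labels)
}

# Plain colour tiles (class colour + noise), for detector tests that do
# not need a slide at all.
colour_tiles <- function(n_per_class, tile_px = 16, noise_sd = 0.03,
                         seed = 5) {
  pal <- fixture_palette()
  set.seed(seed)
  tiles <- list(); labels <- character(0)
  for (cls in names(pal)) {
    for (i in seq_len(n_per_class)) {
      img <- array(rep(pal[[cls]], each = tile_px^2),
                   dim = c(tile_px, tile_px, 3))
      img <- pmin(pmax(img + array(rnorm(length(img), 0, noise_sd),
                                   dim = dim(img)), 0), 1)
      tiles[[length(tiles) + 1L]] <- img
      labels <- c(labels, cls)
    }
  }
  list(tiles = tiles, labels = labels)
}

# A blank white slide of arbitrary size (no noise), for geometry tests.
blank_slide <- function(width, height, tile_size, n_levels = 1) {
  dir <- tempfile("blank")
  dir.create(dir)
  spec <- synthetic_slide_spec(width, height, n_levels = n_levels,
                               regions = list(), noise_sd = 0, seed = 1)
  truth <- generate_slide(spec, file.path(dir, "blank.tiff"))
  set_tile_properties(open_slide(truth$path), tile_size)
}

# A slide whose tile records carry prescribed class probabilities and
# annotation overlap fractions; metric code never touches pixels, so the
# records are fabricated onto a minimal cached slide.
mock_classified_slide <- function(probs, overlaps, class_name = "tumor") {
  if (is.null(fx_cache$tiny)) fx_cache$tiny <- blank_slide(64, 64, 64)
  sl <- fx_cache$tiny
  n <- length(probs)
  sl$tiles <- lapply(seq_len(n), function(k) {
    p <- c(1 - probs[k], probs[k])
    names(p) <- c("other", class_name)
    ov <- overlaps[k]; names(ov) <- class_name
    list(col = k - 1L, row = 0L, x = 0L, y = 0L, overlap = ov,
         foreground_mean = NA_real_, foreground_pass = list(),
         tissue_probs = NULL, classifier_probs = p,
         segmenter_probs = NULL)
  })
  sl$grid_cols <- n
  sl
}

expect_sf_error <- function(expr, class, pattern = NULL) {
  err <- tryCatch({ expr; NULL }, error = function(e) e)
  expect_false(is.null(err), label = "expected an error")
  expect_s3_class(err, class)
  if (!is.null(pattern)) expect_match(conditionMessage(err), pattern)
  invisible(err)
}
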