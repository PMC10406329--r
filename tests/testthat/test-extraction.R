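annotated_aligned <- function() {
  fx <- aligned_bundle()
  annotate_tile_dictionary(fx$slide, fx$annotations)
}

test_that("overlap thresholds gate eligibility inclusively", {
  sl <- blank_slide(128, 64, 64)
  # rectangle covering exactly half of tile (0,0)
  ann <- build_annotation_set(list(
    list(class_name = "half", x = c(0, 32, 32, 0), y = c(0, 0, 64, 64))))
  sl <- annotate_tile_dictionary(sl, ann)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  s1 <- suppressWarnings(extract_annotation_tiles(
    sl, ann, d1, "half", overlap_threshold = 0.3, num_per_class = 10))
  expect_length(attr(s1, "files"), 1)
  s2 <- suppressWarnings(extract_annotation_tiles(
    sl, ann, d2, "half", overlap_threshold = 0.7, num_per_class = 10))
  expect_length(attr(s2, "files"), 0)
  # inclusive at exactly the fraction
  s3 <- suppressWarnings(extract_annotation_tiles(
    sl, ann, d3, "half", overlap_threshold = 0.5, num_per_class = 10))
  expect_length(attr(s3, "files"), 1)
})

test_that("requesting more tiles than available extracts all with a warning", {
  sl <- annotated_aligned()
  fx <- aligned_bundle()
  dir <- tempfile()
  expect_warning(
    stats <- extract_annotation_tiles(sl, fx$annotations, dir, "tissue",
                                      overlap_threshold = 0.5,
                                      num_per_class = 100),
    "Extracting all suitable tiles")
  expect_length(attr(stats, "files"), 2)  # only 2 fully-covered tiles
  expect_sf_error(
    extract_annotation_tiles(sl, fx$annotations, tempfile(), "nonexistent"),
    "slideforge_validation_error", "Unknown class")
})

test_that("extraction is byte-reproducible under a fixed seed", {
  fx <- fixture_bundle()
  sl <- annotate_tile_dictionary(fx$slide, fx$annotations)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- extract_annotation_tiles(sl, fx$annotations, d1, "tissue",
                                 overlap_threshold = 0.3,
                                 num_per_class = 5, seed = 42)
  s2 <- extract_annotation_tiles(sl, fx$annotations, d2, "tissue",
                                 overlap_threshold = 0.3,
                                 num_per_class = 5, seed = 42)
  f1 <- attr(s1, "files"); f2 <- attr(s2, "files")
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  d3 <- tempfile()
  s3 <- extract_annotation_tiles(sl, fx$annotations, d3, "tissue",
                                 overlap_threshold = 0.3,
                                 num_per_class = 5, seed = 43)
  expect_false(identical(basename(f1), basename(attr(s3, "files"))))
})

test_that("the output layout is an image-folder dataset with deterministic names", {
  fx <- fixture_bundle()
  sl <- annotate_tile_dictionary(fx$slide, fx$annotations)
  dir <- tempfile()
  stats <- extract_annotation_tiles(sl, fx$annotations, dir,
                                    c("tissue", "artefact"),
                                    overlap_threshold = 0.3,
                                    num_per_class = 4, extract_masks = TRUE,
                                    other_class_names = "stroma", seed = 1)
  expect_true(dir.exists(file.path(dir, "tiles", "fixture", "tissue")))
  expect_true(dir.exists(file.path(dir, "tiles", "fixture", "artefact")))
  expect_true(dir.exists(file.path(dir, "tiles", "fixture", "stroma")))
  files <- attr(stats, "files")
  expect_match(files, "fixture_(tissue|artefact)_x[0-9]+_y[0-9]+\\.png$")
  # every tile has a matching mask with the same name
  for (f in files) {
    mask_path <- sub("/tiles/", "/masks/", f)
    expect_true(file.exists(mask_path))
    mask <- png::readPNG(mask_path)
    expect_true(all(mask %in% c(0, 1)))  # 8-bit {0, 255} on disk
  }
})

test_that("random unannotated tiles avoid every annotated region", {
  fx <- fixture_bundle()
  sl <- annotate_tile_dictionary(fx$slide, fx$annotations)
  dir <- tempfile()
  stats <- suppressWarnings(extract_random_unannotated_tiles(
    sl, dir, "plain", num_tiles = 10, seed = 3))
  files <- attr(stats, "files")
  expect_gt(length(files), 0)
  for (f in files) {
    m <- regmatches(f, regexec("_x([0-9]+)_y([0-9]+)", f))[[1]]
    x <- as.numeric(m[2]); y <- as.numeric(m[3])
    addr <- tile_addresses(sl)
    k <- which(addr$x == x & addr$y == y)
    expect_true(all(sl$tiles[[k]]$overlap == 0))
  }
})

test_that("the tissue filter excludes background tiles from extraction", {
  fx <- fixture_bundle()
  oracle <- make_oracle_models()$classifier
  sl <- detect_tissue(fx$slide, oracle, detection_level = 0,
                      detection_tile_size = 64)
  sl <- annotate_tile_dictionary(sl, fx$annotations)
  dir <- tempfile()
  stats <- suppressWarnings(extract_random_unannotated_tiles(
    sl, dir, "tissue_like", num_tiles = 200,
    tissue_threshold = 0.995, seed = 2))
  # unannotated tiles that also have >= 99.5% tissue probability: none,
  # since tissue pixels lie inside the annotated disc
  expect_length(attr(stats, "files"), 0)
  # the foreground filter leaves no unannotated dark tiles either
  sl <- detect_foreground(sl, level = 2)
  dir2 <- tempfile()
  expect_warning(
    s2 <- extract_random_unannotated_tiles(sl, dir2, "bg", num_tiles = 5,
                                           foreground_filter = "otsu",
                                           seed = 2),
    class = "slideforge_warning")
  expect_length(attr(s2, "files"), 0)
})

test_that("rasterized masks agree with the geometry", {
  fx <- aligned_bundle()
  sl <- fx$slide
  # tile (0,0) lies fully inside the tissue rectangle
  m <- rasterize_tile_mask(sl, c(0, 0), fx$annotations, "tissue")
  expect_equal(dim(m), c(64, 64))
  expect_true(all(m == 1L))
  # a rectangle over the left half: column sums are 64 then 0
  ann <- build_annotation_set(list(
    list(class_name = "left", x = c(0, 32, 32, 0), y = c(0, 0, 64, 64))))
  m2 <- rasterize_tile_mask(sl, c(0, 0), ann, "left")
  expect_equal(colSums(m2), c(rep(64, 32), rep(0, 32)))
  expect_equal(rowSums(m2), rep(32, 64))
  # absent class: empty mask
  expect_true(all(rasterize_tile_mask(sl, c(0, 0), ann, "nope") == 0L))
})

test_that("mask means track exact overlap fractions", {
  fx <- fixture_bundle()
  sl <- fx$slide
  addr <- tile_addresses(sl)
  set.seed(5)
  for (i in sample(nrow(addr), 10)) {
    a <- c(addr$col[i], addr$row[i])
    fr <- tile_overlap_fraction(sl, a, fx$annotations, "tissue")
    m <- rasterize_tile_mask(sl, a, fx$annotations, "tissue")
    expect_lt(abs(mean(m) - fr), 2 / 64)
  }
})

test_that("multi-class mask stacks match the per-class binary masks", {
  fx <- aligned_bundle()
  sl <- annotate_tile_dictionary(fx$slide, fx$annotations)
  dir <- tempfile()
  suppressWarnings(extract_multiclass_masks(
    sl, fx$annotations, dir, c("tissue", "artefact"),
    overlap_threshold = 0.5, num_per_class = 10, seed = 1))
  stacks <- list.files(file.path(dir, "masks"), recursive = TRUE,
                       full.names = TRUE, pattern = "\\.rds$")
  expect_gt(length(stacks), 0)
  addr <- tile_addresses(sl)
  for (s in stacks) {
    stack <- readRDS(s)
    expect_equal(dim(stack), c(64, 64, 2))
    m <- regmatches(s, regexec("_x([0-9]+)_y([0-9]+)", s))[[1]]
    k <- which(addr$x == as.numeric(m[2]) & addr$y == as.numeric(m[3]))
    a <- c(addr$col[k], addr$row[k])
    expect_equal(stack[, , 1],
                 rasterize_tile_mask(sl, a, fx$annotations, "tissue"))
    expect_equal(stack[, , 2],
                 rasterize_tile_mask(sl, a, fx$annotations, "artefact"))
    # disjoint classes never co-label a pixel
    expect_lte(max(stack[, , 1] + stack[, , 2]), 1)
  }
})

test_that("channel statistics have closed-form means and merge associatively", {
  grey <- array(100 / 255, dim = c(8, 8, 3))
  s <- update_channel_stats(new_channel_stats(), grey)
  out <- finalize_channel_stats(s)
  expect_equal(out$mean, rep(100 / 255, 3))
  expect_equal(out$variance, rep(0, 3))

  bw <- array(rep(c(0, 1), each = 32), dim = c(8, 8, 3))
  out2 <- finalize_channel_stats(update_channel_stats(new_channel_stats(), bw))
  expect_equal(out2$mean, rep(0.5, 3))
  expect_equal(out2$variance, rep(0.25, 3))

  set.seed(8)
  a <- array(runif(48), dim = c(4, 4, 3))
  b <- array(runif(48), dim = c(4, 4, 3))
  merged <- merge_channel_stats(
    update_channel_stats(new_channel_stats(), a),
    update_channel_stats(new_channel_stats(), b))
  joint <- update_channel_stats(update_channel_stats(new_channel_stats(), a), b)
  expect_equal(finalize_channel_stats(merged), finalize_channel_stats(joint))
  expect_sf_error(finalize_channel_stats(new_channel_stats()),
                  "slideforge_validation_error")
})

test_that("eligibility is monotone in every threshold", {
  fx <- fixture_bundle()
  oracle <- make_oracle_models()$classifier
  sl <- detect_tissue(fx$slide, oracle, detection_level = 0,
                      detection_tile_size = 64)
  sl <- annotate_tile_dictionary(sl, fx$annotations)
  count_eligible <- function(ov, tis) {
    sum(vapply(sl$tiles, slideforge:::tile_eligible, logical(1),
               "tissue", ov, tis, NULL))
  }
  for (tis in list(NULL, 0.5, 0.995)) {
    ns <- vapply(c(0.1, 0.3, 0.5, 0.8, 1), count_eligible, numeric(1), tis)
    expect_true(all(diff(ns) <= 0))
  }
  expect_lte(count_eligible(0.3, 0.995), count_eligible(0.3, NULL))
})
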