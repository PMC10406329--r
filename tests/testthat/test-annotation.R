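write_geojson_fixture <- function(features) {
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

square_feature <- function(cls, x0, y0, side) {
  ring <- list(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
               c(x0, y0 + side), c(x0, y0))
  list(type = "Feature",
       properties = list(classification = list(name = cls)),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

test_that("GeoJSON polygons parse with QuPath-style classes", {
  path <- write_geojson_fixture(list(square_feature("tumor", 0, 0, 100)))
  raw <- parse_geojson(path)
  expect_length(raw, 1)
  expect_equal(raw[[1]]$class_name, "tumor")
  expect_length(raw[[1]]$x, 4)  # closing vertex removed

  empty <- write_geojson_fixture(list())
  expect_length(parse_geojson(empty), 0)

  line <- write_geojson_fixture(list(list(
    type = "Feature", properties = list(name = "l"),
    geometry = list(type = "LineString",
                    coordinates = list(c(0, 0), c(1, 1))))))
  expect_sf_error(parse_geojson(line), "slideforge_unsupported_geometry")

  noclass <- write_geojson_fixture(list(list(
    type = "Feature", properties = list(),
    geometry = list(type = "Polygon", coordinates = list(list(
      c(0, 0), c(1, 0), c(1, 1), c(0, 0)))))))
  expect_sf_error(parse_geojson(noclass), "slideforge_parse_error", "Feature 1")
})

test_that("ASAP XML annotations parse in document order", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<ASAP_Annotations><Annotations>',
    '<Annotation Name="A0" Type="Polygon" PartOfGroup="normal">',
    '<Coordinates>',
    '<Coordinate Order="0" X="10" Y="10"/>',
    '<Coordinate Order="1" X="60" Y="10"/>',
    '<Coordinate Order="2" X="60" Y="40"/>',
    '<Coordinate Order="3" X="10" Y="40"/>',
    '</Coordinates></Annotation>',
    '<Annotation Name="A1" Type="Polygon" PartOfGroup="tumor">',
    '<Coordinates>',
    '<Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="5" Y="0"/>',
    '<Coordinate Order="2" X="5" Y="5"/>',
    '</Coordinates></Annotation>',
    '</Annotations></ASAP_Annotations>'), path)
  raw <- parse_asap_xml(path)
  expect_length(raw, 2)
  expect_equal(raw[[1]]$class_name, "normal")
  expect_equal(raw[[2]]$class_name, "tumor")
  expect_equal(raw[[1]]$x, c(10, 60, 60, 10))

  trunc <- tempfile(fileext = ".xml")
  writeLines('<ASAP_Annotations><Annotations><Annotation', trunc)
  expect_sf_error(parse_asap_xml(trunc), "slideforge_parse_error")
})

test_that("doughnut-hole subtraction removes the hole area", {
  raw <- list(
    list(class_name = "tumor", x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
    list(class_name = "doughnut_holes", x = c(25, 75, 75, 25),
         y = c(25, 25, 75, 75)))
  ann <- build_annotation_set(raw, negative_class = "doughnut_holes")
  expect_equal(annotation_area(ann, "tumor"), 7500)
  expect_false("doughnut_holes" %in% names(ann$classes))

  # disjoint hole: no effect beyond dropping the hole class
  raw2 <- list(
    list(class_name = "tumor", x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
    list(class_name = "doughnut_holes", x = c(200, 250, 250, 200),
         y = c(200, 200, 250, 250)))
  ann2 <- build_annotation_set(raw2, negative_class = "doughnut_holes")
  expect_equal(annotation_area(ann2, "tumor"), 10000)
})

test_that("self-intersecting rings are rejected with their centroid", {
  bowtie <- list(list(class_name = "bad",
                      x = c(0, 10, 0, 10), y = c(0, 10, 10, 0)))
  err <- expect_sf_error(build_annotation_set(bowtie),
                         "slideforge_self_intersection",
                         "check to see if it self-intersects")
  expect_match(conditionMessage(err), "\\(5\\.0, 5\\.0\\)")
})

test_that("a class swallowed whole by the negative class is dropped with a warning", {
  raw <- list(
    list(class_name = "tiny", x = c(40, 60, 60, 40), y = c(40, 40, 60, 60)),
    list(class_name = "doughnut_holes", x = c(0, 100, 100, 0),
         y = c(0, 0, 100, 100)))
  expect_warning(ann <- build_annotation_set(raw,
                                             negative_class = "doughnut_holes"),
                 class = "slideforge_zero_area")
  expect_false("tiny" %in% names(ann$classes))
})

test_that("tile overlap fractions are exact area ratios", {
  sl <- blank_slide(100, 50, 50)
  # left 30 x 50 of tile (0,0)
  ann <- build_annotation_set(list(
    list(class_name = "stripe", x = c(0, 30, 30, 0), y = c(0, 0, 50, 50)),
    list(class_name = "big", x = c(-10, 110, 110, -10),
         y = c(-10, -10, 60, 60)),
    list(class_name = "far", x = c(500, 520, 520, 500),
         y = c(500, 500, 520, 520))))
  expect_equal(tile_overlap_fraction(sl, c(0, 0), ann, "stripe"), 0.6)
  expect_equal(tile_overlap_fraction(sl, c(0, 0), ann, "big"), 1)
  expect_equal(tile_overlap_fraction(sl, c(0, 0), ann, "far"), 0)
  expect_equal(tile_overlap_fraction(sl, c(0, 0), ann, "absent"), 0)
})

test_that("same-class overlapping annotations are unioned, not double-counted", {
  sl <- blank_slide(100, 50, 50)
  ann <- build_annotation_set(list(
    list(class_name = "c", x = c(0, 30, 30, 0), y = c(0, 0, 50, 50)),
    list(class_name = "c", x = c(10, 40, 40, 10), y = c(0, 0, 50, 50))))
  expect_equal(tile_overlap_fraction(sl, c(0, 0), ann, "c"), 0.8)
})

test_that("annotating the tile dictionary covers every tile and conserves area", {
  fx <- aligned_bundle()
  sl <- annotate_tile_dictionary(fx$slide, fx$annotations)
  addr <- tile_addresses(sl)
  fr <- vapply(seq_len(nrow(addr)), function(i)
    sl$tiles[[i]]$overlap[["tissue"]], numeric(1))
  # the 128x64 tissue rectangle covers exactly tiles (0,0) and (1,0)
  inside <- addr$x < 128 & addr$y < 64
  expect_true(all(fr[inside] == 1))
  expect_true(all(fr[!inside] == 0))
  # conservation: fractions times tile area total the class area
  expect_equal(sum(fr) * 64^2, annotation_area(fx$annotations, "tissue"))
  art <- vapply(seq_len(nrow(addr)), function(i)
    sl$tiles[[i]]$overlap[["artefact"]], numeric(1))
  expect_equal(sum(art) * 64^2, annotation_area(fx$annotations, "artefact"))
})

test_that("hole subtraction area matches a Monte-Carlo oracle within 0.5%", {
  set.seed(31)
  for (rep in 1:5) {
    outer_ring <- random_star_polygon(200, 200, 80, 150, n = 14)
    hole <- random_star_polygon(200 + runif(1, -40, 40),
                                200 + runif(1, -40, 40), 20, 45, n = 10)
    ann <- build_annotation_set(
      list(list(class_name = "c", x = outer_ring$x, y = outer_ring$y),
           list(class_name = "neg", x = hole$x, y = hole$y)),
      negative_class = "neg")
    exact <- annotation_area(ann, "c")
    mc <- mc_region_area(list(outer_ring), list(hole), n = 4e5)
    expect_lt(abs(exact - mc), 0.005 * exact)
  }
})

test_that("overlap fractions agree with a supersampled rasterization oracle", {
  fx <- fixture_bundle()
  sl <- fx$slide
  disc <- fx$truth$class_polygons$tissue[[1]]
  addr <- tile_addresses(sl)
  set.seed(17)
  for (i in sample(nrow(addr), 12)) {
    exact <- tile_overlap_fraction(sl, c(addr$col[i], addr$row[i]),
                                   fx$annotations, "tissue")
    approx <- raster_overlap_fraction(addr$x[i], addr$y[i], 64, disc,
                                      super = 2L)
    expect_lt(abs(exact - approx), 1 / 64)
  }
})

test_that("writing and re-parsing annotations preserves classes and vertices", {
  fx <- fixture_bundle()
  gj <- parse_geojson(fx$geojson)
  xml <- parse_asap_xml(fx$xml)
  classes <- sort(vapply(fx$truth$class_polygons, function(p) 1L,
                         integer(1)))
  expect_setequal(vapply(gj, `[[`, character(1), "class_name"),
                  names(fx$truth$class_polygons))
  expect_equal(sort(vapply(gj, function(a) length(a$x), integer(1))),
               sort(vapply(xml, function(a) length(a$x), integer(1))))
  expect_equal(vapply(gj, `[[`, character(1), "class_name"),
               vapply(xml, `[[`, character(1), "class_name"))
})
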