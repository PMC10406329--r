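# Annotation parsing (GeoJSON, ASAP XML) and per-tile overlap fractions.
# Annotation coordinates are level-0 pixels throughout.

normalize_ring <- function(x, y) {
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  list(x = as.numeric(x[keep]), y = as.numeric(y[keep]))
}

new_raw_annotation <- function(class_name, x, y) {
  r <- normalize_ring(x, y)
  list(class_name = class_name, x = r$x, y = r$y)
}

#' Parse a GeoJSON annotation file
#'
#' Reads a QuPath-style GeoJSON FeatureCollection of polygon annotations.
#' The class name is taken from `properties.classification.name`, falling
#' back to `properties.name`. MultiPolygons are split into one annotation
#' per member polygon; interior rings of the source geometry are ignored
#' here (hole handling is done by class, see [build_annotation_set()]).
#'
#' @param path GeoJSON file path.
#' @return List of raw annotations, each `list(class_name, x, y)` with
#'   vertices in level-0 pixels (closing vertex removed).
#' @export
parse_geojson <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path), error = function(e)
    sf_stop(sprintf("Cannot parse `%s` as GeoJSON: %s", path,
                    conditionMessage(e)), "slideforge_parse_error"))
  feats <- if (identical(doc$type, "FeatureCollection")) doc$features
           else sf_stop(sprintf("`%s` is not a GeoJSON FeatureCollection", path),
                        "slideforge_parse_error")
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    cls <- f$properties$classification$name %||% f$properties$name
    if (is.null(cls))
      sf_stop(sprintf(
        "Feature %d has no class: expected properties.classification.name or properties.name",
        i), "slideforge_parse_error")
    geom <- f$geometry
    rings <- switch(
      geom$type %||% "missing",
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1),
      sf_stop(sprintf(
        "Feature %d has unsupported geometry type '%s' (only Polygon and MultiPolygon)",
        i, geom$type %||% "missing"), "slideforge_unsupported_geometry"))
    for (ring in rings) {
      x <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
      y <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
      out[[length(out) + 1L]] <- new_raw_annotation(cls, x, y)
    }
  }
  out
}

#' Parse an ASAP XML annotation file
#'
#' Reads the XML dialect written by ASAP:
#' `<ASAP_Annotations><Annotations><Annotation PartOfGroup=...>` with
#' ordered `<Coordinate Order X Y/>` children. One raw annotation per
#' `Annotation` element, vertices in document order.
#'
#' @param path XML file path.
#' @return List of raw annotations as in [parse_geojson()].
#' @export
parse_asap_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    sf_stop(sprintf("Cannot parse `%s` as XML: %s", path,
                    conditionMessage(e)), "slideforge_parse_error"))
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  out <- list()
  for (node in nodes) {
    cls <- xml2::xml_attr(node, "PartOfGroup")
    if (is.na(cls)) cls <- xml2::xml_attr(node, "Group")
    if (is.na(cls)) cls <- xml2::xml_attr(node, "Name")
    coords <- xml2::xml_find_all(node, ".//Coordinate")
    if (length(coords) < 3)
      sf_stop(sprintf(
        "Annotation '%s' has %d coordinates; a polygon needs at least 3",
        cls, length(coords)), "slideforge_validation_error")
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    if (!anyNA(ord)) coords <- coords[order(ord)]
    out[[length(out) + 1L]] <- new_raw_annotation(
      cls,
      as.numeric(xml2::xml_attr(coords, "X")),
      as.numeric(xml2::xml_attr(coords, "Y")))
  }
  out
}

#' Build an annotation set with doughnut holes subtracted
#'
#' Groups raw annotations by class, unions same-class polygons (so
#' overlapping annotations of one class are not double-counted), and
#' geometrically subtracts every ring of the negative ("doughnut hole")
#' class from every other class's region. Annotations reduced to zero
#' area by the subtraction are dropped with a warning.
#'
#' @param raw List of raw annotations from [parse_geojson()] or
#'   [parse_asap_xml()].
#' @param classes_to_add Optional class whitelist; the negative class is
#'   handled regardless of this list and never appears in the output.
#' @param negative_class Optional class name whose rings are subtracted
#'   from all other classes.
#' @return Object of class `slideforge_annotations`: per class, a
#'   polyclip-normalized region (outer rings plus holes, winding-encoded).
#' @export
build_annotation_set <- function(raw, classes_to_add = NULL,
                                 negative_class = NULL) {
  for (a in raw) {
    if (length(a$x) < 3)
      sf_stop(sprintf("Annotation of class '%s' has fewer than 3 distinct vertices",
                      a$class_name), "slideforge_validation_error")
    if (!ring_is_simple(a)) {
      cen <- ring_centroid(a)
      sf_stop(sprintf(
        "Annotation with centroid (%.1f, %.1f) produces a self-intersecting ring instead of a polygon; check to see if it self-intersects.",
        cen[1], cen[2]), "slideforge_self_intersection")
    }
  }
  classes <- unique(vapply(raw, `[[`, character(1), "class_name"))
  neg_rings <- list()
  if (!is.null(negative_class)) {
    neg_rings <- lapply(Filter(function(a) a$class_name == negative_class, raw),
                        function(a) list(x = a$x, y = a$y))
    classes <- setdiff(classes, negative_class)
  }
  if (!is.null(classes_to_add)) classes <- intersect(classes, classes_to_add)
  out <- list()
  for (cls in classes) {
    rings <- lapply(Filter(function(a) a$class_name == cls, raw),
                    function(a) list(x = a$x, y = a$y))
    region <- region_union_self(rings)
    if (length(neg_rings) > 0) {
      before <- region_area(region)
      region <- region_op(region, region_union_self(neg_rings), "minus")
      if (before > 0 && region_area(region) <= 0) {
        sf_warn(sprintf(
          "Class '%s' was reduced to zero area by subtraction of '%s' and dropped",
          cls, negative_class), "slideforge_zero_area")
        next
      }
    }
    out[[cls]] <- region
  }
  structure(list(classes = out), class = "slideforge_annotations")
}

#' @export
print.slideforge_annotations <- function(x, ...) {
  cat("<slideforge_annotations>\n")
  for (cls in names(x$classes))
    cat(sprintf("  %s: %d rings, area %.1f px^2\n", cls,
                length(x$classes[[cls]]), region_area(x$classes[[cls]])))
  invisible(x)
}

#' Annotated area of one class
#' @param annotations A `slideforge_annotations`.
#' @param class_name Class to measure.
#' @return Area in level-0 square pixels (0 for an absent class).
#' @export
annotation_area <- function(annotations, class_name) {
  region_area(annotations$classes[[class_name]] %||% list())
}

# Level-0 rectangle of a tile record given the slide's active level.
tile_rect_level0 <- function(slide, rec) {
  ds <- slide$downsample[slide$level + 1L]
  rect_ring(rec$x * ds, rec$y * ds,
            (rec$x + slide$tile_size) * ds, (rec$y + slide$tile_size) * ds)
}

#' Fraction of a tile covered by a class's annotations
#'
#' Exact polygon clipping of the class region (same-class union, holes
#' excluded) against the tile rectangle, divided by the tile area.
#'
#' @param slide A slide with tile properties set.
#' @param address Tile `(col, row)` pair.
#' @param annotations A `slideforge_annotations` (level-0 coordinates).
#' @param class_name Class to measure; an absent class gives 0.
#' @return Fraction in `[0, 1]`.
#' @export
tile_overlap_fraction <- function(slide, address, annotations, class_name) {
  require_tiling(slide)
  a <- resolve_address(slide, address)
  rec <- slide$tiles[[tile_key(a["col"], a["row"])]]
  region <- annotations$classes[[class_name]]
  if (is.null(region) || length(region) == 0) return(0)
  rect <- tile_rect_level0(slide, rec)
  tile_area <- (slide$tile_size * slide$downsample[slide$level + 1L])^2
  min(1, region_intersect_area(region, list(rect)) / tile_area)
}

#' Fill per-class overlap fractions into the tile dictionary
#'
#' @param slide A slide with tile properties set.
#' @param annotations A `slideforge_annotations`.
#' @return The slide; every tile record's `overlap` becomes a named
#'   vector with one fraction in `[0, 1]` per annotation class.
#' @export
annotate_tile_dictionary <- function(slide, annotations) {
  require_tiling(slide)
  classes <- names(annotations$classes)
  ds <- slide$downsample[slide$level + 1L]
  tile_area <- (slide$tile_size * ds)^2
  for (k in seq_along(slide$tiles)) {
    rec <- slide$tiles[[k]]
    rect <- list(tile_rect_level0(slide, rec))
    fr <- vapply(classes, function(cls) {
      min(1, region_intersect_area(annotations$classes[[cls]], rect) /
            tile_area)
    }, numeric(1))
    names(fr) <- classes
    slide$tiles[[k]]$overlap <- fr
  }
  slide
}
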