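#' Read a vessel annotation from a GeoJSON feature collection
#'
#' Accepts the annotation-export shape produced by whole-slide annotation
#' tools: an RFC 7946 `FeatureCollection` of `Polygon` features, each
#' classified (via `properties$classification$name` or a plain
#' `properties$classification` string) as `ideal_lumen` (exactly one) or
#' `residual_lumen` (zero or more), with the scan calibration in the
#' top-level `properties.microns_per_pixel`. Classification matching is
#' case-insensitive. Coordinates are 0-based pixel positions with y
#' increasing downward (image convention, not geographic). Explicitly
#' closed rings are un-closed internally.
#'
#' @param path Path to a GeoJSON file.
#' @param section_id Section identifier; defaults to the file name.
#' @return A [vessel_annotation()].
#' @export
read_vessel_geojson <- function(path, section_id = NULL) {
  if (!file.exists(path)) abort_parse("annotation file not found", file = path)
  g <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) abort_parse(paste0("not valid JSON: ", conditionMessage(e)),
                                                file = path))
  if (is.null(g$type) || !identical(g$type, "FeatureCollection")) {
    abort_parse("expected a GeoJSON FeatureCollection", file = path)
  }
  mpp <- g$properties$microns_per_pixel
  if (is.null(mpp)) {
    abort_parse("missing calibration: top-level properties.microns_per_pixel", file = path)
  }
  ideal <- NULL
  residual <- list()
  for (i in seq_along(g$features)) {
    f <- g$features[[i]]
    locus <- sprintf("feature %d", i)
    cls <- f$properties$classification
    if (is.list(cls)) cls <- cls$name
    if (is.null(cls) || !nzchar(cls)) {
      abort_parse("unclassified feature (need ideal_lumen or residual_lumen)",
                  file = path, locus = locus)
    }
    cls <- tolower(cls)
    if (!cls %in% c("ideal_lumen", "residual_lumen")) {
      abort_parse(sprintf("unknown classification '%s'", cls), file = path, locus = locus)
    }
    geom <- f$geometry
    if (is.null(geom$type) || !identical(geom$type, "Polygon")) {
      abort_parse(sprintf("non-polygon geometry '%s'", geom$type %||% "<missing>"),
                  file = path, locus = locus)
    }
    rings <- geom$coordinates
    if (length(rings) != 1) {
      abort_parse("polygons with interior rings (holes) are not supported",
                  file = path, locus = locus)
    }
    xy <- do.call(rbind, lapply(rings[[1]], function(pt) c(pt[[1]], pt[[2]])))
    poly <- tryCatch(vessel_polygon(xy),
                     lumen_validation_error = function(e) {
                       abort_parse(conditionMessage(e), file = path, locus = locus)
                     })
    if (cls == "ideal_lumen") {
      if (!is.null(ideal)) abort_parse("more than one ideal_lumen feature", file = path,
                                       locus = locus)
      ideal <- poly
    } else {
      residual[[length(residual) + 1L]] <- poly
    }
  }
  if (is.null(ideal)) abort_parse("no feature classified ideal_lumen", file = path)
  if (is.null(section_id)) {
    section_id <- g$properties$section_id %||%
      tools::file_path_sans_ext(basename(path))
  }
  vessel_annotation(as.character(section_id), ideal, region_set(residual),
                    microns_per_pixel = as.numeric(mpp))
}

#' Write a vessel annotation as a GeoJSON feature collection
#'
#' Inverse of [read_vessel_geojson()]: one feature per polygon, rings
#' explicitly closed, classification names written canonically lower-case
#' as `ideal_lumen` / `residual_lumen`, calibration and section id in the
#' top-level `properties`.
#'
#' @param a A [vessel_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vessel_geojson <- function(a, path) {
  if (!inherits(a, "vessel_annotation")) {
    abort_validation("write_vessel_geojson expects a vessel_annotation")
  }
  ring <- function(p) {
    # close the ring explicitly per the GeoJSON convention
    xs <- c(p$x, p$x[1])
    ys <- c(p$y, p$y[1])
    list(mapply(function(x, y) c(x, y), xs, ys, SIMPLIFY = FALSE))
  }
  feat <- function(p, cls) {
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = ring(p)),
         properties = list(classification = list(name = cls)))
  }
  features <- c(list(feat(a$ideal_lumen, "ideal_lumen")),
                lapply(a$residual_lumen, feat, cls = "residual_lumen"))
  fc <- list(type = "FeatureCollection",
             properties = list(microns_per_pixel = a$calibration$microns_per_pixel,
                               section_id = a$section_id),
             features = features)
  ok <- tryCatch({
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_parse("cannot write annotation file", file = path)
  invisible(path)
}
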