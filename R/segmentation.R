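#' Segment a vessel cross-section image into an annotation
#'
#' Recovers a [vessel_annotation()] from a single-channel raster of an
#' elastic-contrast cross-section, automating the manual annotation step:
#' the internal elastic lamina is found as the single dark closed ring
#' (intensity thresholding, connected components, hole filling), the ideal
#' lumen is the polygon traced along the ring's inner boundary, and the
#' residual lumen is the set of bright connected components inside that
#' contour, each at least `min_channel_area` px^2 (noise-speckle filter).
#' Contours are traced at half-pixel resolution on the mask boundary and
#' simplified with a 0.5 px tolerance.
#'
#' Thresholds are parameter-free on the three-level synthetic images: the
#' ring threshold is an Otsu split restricted to the darkest intensity
#' mode, and the lumen threshold is an Otsu split of the pixels inside the
#' ring. When the interior is effectively unimodal (a fully patent or
#' fully occluded vessel leaves nothing to split) the whole interior is
#' classified as residual or plaque by comparing it with the background
#' outside the ring.
#'
#' Real scanned whole-slide images are unsupported input: the image reader
#' rejects multi-channel rasters, and no stain deconvolution is attempted.
#'
#' @param image An integer grey matrix (rows = y) in `[0, 255]`, e.g. from
#'   [render_vessel()] or [read_vessel_image()], or a path to a PNG/TIFF.
#' @param microns_per_pixel Calibration of the image; defaults to the
#'   matrix attribute set by [render_vessel()].
#' @param min_channel_area Minimum residual-channel area in px^2.
#' @param simplify_tol Polygon simplification tolerance in px.
#' @param section_id Identifier for the resulting annotation.
#' @return A [vessel_annotation()].
#' @export
segment_vessel <- function(image, microns_per_pixel = NULL,
                           min_channel_area = 25, simplify_tol = 0.5,
                           section_id = NULL) {
  if (is.character(image)) {
    if (is.null(section_id)) section_id <- tools::file_path_sans_ext(basename(image))
    image <- read_vessel_image(image)
  }
  if (is.null(microns_per_pixel)) microns_per_pixel <- attr(image, "microns_per_pixel")
  if (is.null(microns_per_pixel)) {
    abort_validation("microns_per_pixel is required (not carried by the image)")
  }
  if (length(dim(image)) != 2) {
    abort_segmentation("multi-channel image: only single-channel rasters are supported")
  }
  if (is.null(section_id)) section_id <- "segmented"
  v <- image / 255
  if (diff(range(v)) < 0.02) {
    abort_segmentation("no closed lamina ring found (image is essentially flat)")
  }
  # EBImage frame: dim1 = x (image column), dim2 = y (row)
  ebi <- EBImage::Image(t(v))

  t_ring <- darkest_mode_threshold(as.numeric(v))
  dark <- ebi < t_ring
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(as.integer(lab))
  rings <- integer(0)
  for (i in seq_along(sizes)) {
    if (sizes[i] < 40) next # a lamina ring is never this small
    comp <- lab == i
    interior_px <- sum(EBImage::fillHull(comp)) - sizes[i]
    if (interior_px >= 100) rings <- c(rings, i)
  }
  if (length(rings) == 0) {
    abort_segmentation("no closed lamina ring found")
  }
  if (length(rings) > 1) {
    abort_segmentation(sprintf(
      "multiple candidate lamina rings found (component sizes: %s); expected exactly one vessel",
      paste(sizes[rings], collapse = ", ")))
  }
  ring_mask <- lab == rings
  interior <- EBImage::fillHull(ring_mask) & !ring_mask
  ideal <- trace_polygon(interior, simplify_tol)

  vi <- as.numeric(ebi)[as.logical(interior)]
  t_lum <- as.numeric(EBImage::otsu(EBImage::Image(matrix(vi, ncol = 1))))
  lo_cls <- vi[vi <= t_lum]
  hi_cls <- vi[vi > t_lum]
  bimodal <- length(lo_cls) > 0 && length(hi_cls) > 0 &&
    (mean(hi_cls) - mean(lo_cls)) >
      2 * sqrt(stats::weighted.mean(c(safe_var(lo_cls), safe_var(hi_cls)),
                                    c(length(lo_cls), length(hi_cls)))) + 2 / 255

  residual <-
    if (!bimodal) {
      outside <- !(EBImage::fillHull(ring_mask) | dark)
      bg_level <- stats::median(as.numeric(ebi)[as.logical(outside)])
      if (stats::median(vi) > bg_level) region_set(ideal) else region_set()
    } else {
      bright <- interior & (ebi > t_lum)
      blab <- EBImage::bwlabel(bright)
      bsizes <- tabulate(as.integer(blab))
      keep <- which(bsizes >= min_channel_area)
      polys <- lapply(keep, function(i) trace_polygon(blab == i, simplify_tol))
      clip_regions(region_set(polys), ideal)
    }

  vessel_annotation(section_id, ideal, residual,
                    microns_per_pixel = microns_per_pixel)
}

# Otsu split restricted to the darkest intensity mode: a first global Otsu
# separates the image; if the below-threshold pixels are themselves clearly
# bimodal (the dark ring plus a mid-grey mode landed together), a second
# Otsu on them isolates the darkest mode.
darkest_mode_threshold <- function(v) {
  t0 <- as.numeric(EBImage::otsu(EBImage::Image(matrix(v, ncol = 1))))
  vd <- v[v <= t0]
  if (length(vd) < 20 || diff(range(vd)) < 0.02) return(t0)
  t1 <- as.numeric(EBImage::otsu(EBImage::Image(matrix(vd, ncol = 1)),
                                 range = range(vd)))
  lo <- vd[vd <= t1]
  hi <- vd[vd > t1]
  if (length(lo) == 0 || length(hi) == 0) return(t0)
  sd_w <- sqrt(stats::weighted.mean(c(safe_var(lo), safe_var(hi)),
                                    c(length(lo), length(hi))))
  if ((mean(hi) - mean(lo)) > 2 * sd_w + 2 / 255) t1 else t0
}

safe_var <- function(z) if (length(z) < 2) 0 else stats::var(z)

# Trace the boundary of a binary mask as a simple polygon: contour through
# boundary pixel centres, pushed outward by half a pixel so the polygon
# follows the outer pixel edges, then Douglas-Peucker simplified and
# repaired to a single simple ring.
trace_polygon <- function(mask, simplify_tol = 0.5) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0) abort_segmentation("empty mask; nothing to trace")
  # keep the largest traced object
  areas <- vapply(oc, function(m) {
    abs(shoelace_area(list(x = m[, 1], y = m[, 2])))
  }, numeric(1))
  m <- oc[[which.max(areas)]]
  p <- list(x = m[, 1] + 0.5, y = m[, 2] + 0.5)
  off <- polyclip::polyoffset(list(p), 0.5, jointype = "miter", miterlim = 2)
  q <- off[[which.max(vapply(off, function(r) abs(shoelace_area(r)), numeric(1)))]]
  q <- simplify_ring(structure(q, class = "vessel_polygon"), tol = simplify_tol)
  simp <- polyclip::polysimplify(list(x = q$x, y = q$y), filltype = "evenodd")
  q <- simp[[which.max(vapply(simp, function(r) abs(shoelace_area(r)), numeric(1)))]]
  vessel_polygon(q$x, q$y)
}
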