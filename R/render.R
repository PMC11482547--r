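# Rendering synthetic vessels to single-channel 8-bit rasters.
# Grey palette (8-bit): elastic lamina ring 30, plaque 130, background 200,
# residual lumen 235 — dark closed ring, mid-grey plaque, bright channels,
# mimicking the tonal structure of an elastic-stained section.
GREY_RING <- 30L
GREY_PLAQUE <- 130L
GREY_BACKGROUND <- 200L
GREY_RESIDUAL <- 235L

# Logical mask [ny, nx] of pixels whose centres (x + 0.5, y + 0.5), 0-based,
# fall inside any of the given polygons (even-odd).
rasterize_mask <- function(polys, nx, ny) {
  mask <- matrix(FALSE, ny, nx)
  if (inherits(polys, "vessel_polygon")) polys <- list(polys)
  for (p in polys) {
    x0 <- max(0L, floor(min(p$x) - 1))
    x1 <- min(nx - 1L, ceiling(max(p$x)))
    y0 <- max(0L, floor(min(p$y) - 1))
    y1 <- min(ny - 1L, ceiling(max(p$y)))
    if (x1 < x0 || y1 < y0) next
    xs <- seq(x0, x1) + 0.5
    ys <- seq(y0, y1) + 0.5
    grid <- list(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
    inside <- polyclip::pointinpolygon(grid, list(x = p$x, y = p$y)) != 0
    sub <- matrix(inside, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    rows <- (y0 + 1L):(y1 + 1L)
    cols <- (x0 + 1L):(x1 + 1L)
    mask[rows, cols] <- mask[rows, cols] | sub
  }
  mask
}

#' Render a synthetic vessel to an 8-bit raster image
#'
#' Draws the internal elastic lamina as a dark closed ring immediately
#' outside the ideal-lumen contour (so the ring's inner boundary is the
#' contour itself), fills plaque (ideal minus residual) mid-grey and the
#' residual channels bright, and adds Gaussian intensity noise of standard
#' deviation `spec$noise_sd` (seeded by `spec$seed`; rendering is
#' deterministic given spec and seed).
#'
#' @param vessel A result of [generate_vessel()] (or a
#'   [vessel_annotation()] when `spec` is supplied separately).
#' @param spec The [vessel_spec()]; taken from `vessel` when omitted.
#' @param ring_px Ring thickness in pixels.
#' @return An integer matrix (rows = y, columns = x) of grey values in
#'   `[0, 255]`, with the calibration attached as attribute
#'   `"microns_per_pixel"`.
#' @export
render_vessel <- function(vessel, spec = NULL, ring_px = 4) {
  if (is.list(vessel) && !is.null(vessel$annotation)) {
    if (is.null(spec)) spec <- vessel$spec
    vessel <- vessel$annotation
  }
  if (!inherits(vessel, "vessel_annotation") || is.null(spec)) {
    abort_validation("render_vessel needs a generated vessel (annotation + spec)")
  }
  ideal <- vessel$ideal_lumen
  outer <- from_polyclip(polyclip::polyoffset(list(list(x = ideal$x, y = ideal$y)),
                                              ring_px, jointype = "round"))[[1]]
  pad <- 8
  nx <- as.integer(ceiling(max(outer$x) + pad))
  ny <- as.integer(ceiling(max(outer$y) + pad))
  if (min(outer$x) < 1 || min(outer$y) < 1) {
    abort_validation("vessel does not fit the canvas; move lamina_center away from the origin")
  }
  residual <- clip_regions(canonicalize_regions(vessel$residual_lumen), ideal)
  img <- matrix(GREY_BACKGROUND, ny, nx)
  m_outer <- rasterize_mask(outer, nx, ny)
  m_ideal <- rasterize_mask(ideal, nx, ny)
  m_res <- if (length(residual)) rasterize_mask(residual, nx, ny) else
    matrix(FALSE, ny, nx)
  img[m_outer & !m_ideal] <- GREY_RING
  img[m_ideal] <- GREY_PLAQUE
  img[m_res & m_ideal] <- GREY_RESIDUAL
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed, {
      img + round(stats::rnorm(length(img), 0, spec$noise_sd))
    })
    img[img < 0] <- 0L
    img[img > 255] <- 255L
  }
  storage.mode(img) <- "integer"
  attr(img, "microns_per_pixel") <- spec$microns_per_pixel
  img
}

#' Write / read single-channel vessel images
#'
#' PNG or TIFF is chosen from the file extension. Images are written as
#' 8-bit greyscale; the reader rejects multi-channel input (real scanned
#' colour slides are explicitly unsupported) and returns an integer matrix
#' of grey values in `[0, 255]`.
#'
#' @param img Integer matrix from [render_vessel()].
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_vessel_image()` returns `path` invisibly;
#'   `read_vessel_image()` returns the image matrix.
#' @export
write_vessel_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- img / 255
  attributes(m) <- list(dim = dim(img))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    abort_usage(sprintf("unsupported image extension '.%s' (use png or tiff)", ext))
  }
  invisible(path)
}

#' @rdname write_vessel_image
#' @export
read_vessel_image <- function(path) {
  if (!file.exists(path)) abort_parse("image file not found", file = path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    out <- tiff::readTIFF(path)
    if (is.list(out)) out[[1]] else out
  } else {
    abort_usage(sprintf("unsupported image extension '.%s' (use png or tiff)", ext))
  }
  if (length(dim(m)) == 3) {
    if (dim(m)[3] > 1) {
      abort_segmentation("multi-channel image: only single-channel elastic-contrast rasters are supported")
    }
    m <- m[, , 1]
  }
  img <- round(m * 255)
  storage.mode(img) <- "integer"
  img
}
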