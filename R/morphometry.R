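#' Vessel annotation: the geometric record of one coronary section
#'
#' Couples the ideal-lumen contour (the ring of the internal elastic lamina,
#' i.e. the lumen the vessel would have without plaque) with the set of
#' residual-lumen channels left patent by the plaque, plus the scanner
#' calibration needed to express areas in mm^2.
#'
#' @param section_id Character identifier of the section.
#' @param ideal_lumen Ideal-lumen polygon (pixel coordinates).
#' @param residual_lumen A [region_set()] of residual channels (may be
#'   empty for a fully occluded vessel).
#' @param microns_per_pixel Strictly positive scan calibration; one pixel
#'   covers `(microns_per_pixel / 1000)^2` mm^2.
#' @return An object of class `vessel_annotation`.
#' @seealso [measure_stenosis()]
#' @export
vessel_annotation <- function(section_id, ideal_lumen, residual_lumen = region_set(),
                              microns_per_pixel) {
  if (!is.character(section_id) || length(section_id) != 1 || is.na(section_id)) {
    abort_validation("section_id must be a single character string")
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    abort_validation("microns_per_pixel must be a single strictly positive number")
  }
  if (!inherits(ideal_lumen, "vessel_polygon")) ideal_lumen <- vessel_polygon(ideal_lumen)
  if (!inherits(residual_lumen, "region_set")) residual_lumen <- region_set(residual_lumen)
  structure(
    list(section_id = section_id,
         ideal_lumen = ideal_lumen,
         residual_lumen = residual_lumen,
         calibration = list(microns_per_pixel = microns_per_pixel)),
    class = "vessel_annotation"
  )
}

#' @export
print.vessel_annotation <- function(x, ...) {
  cat(sprintf("<vessel_annotation '%s': ideal %d vertices, %d residual region(s), %.3g um/px>\n",
              x$section_id, length(x$ideal_lumen$x), length(x$residual_lumen),
              x$calibration$microns_per_pixel))
  invisible(x)
}

mm2_per_px2 <- function(microns_per_pixel) (microns_per_pixel / 1000)^2

#' Measure percent lumen occlusion of an annotated section
#'
#' The computational core of digital stenosis assessment. Residual regions
#' are first canonicalized (overlaps merged) and clipped to the ideal lumen
#' — hand annotations routinely overlap and leak, so they are repaired, not
#' rejected. Areas are converted to mm^2, the percent residual lumen is the
#' area ratio, and the lumen occlusion percentage is
#' `LO = 100 - percent residual`. Risk flags follow [classify_risk()].
#'
#' @param a A [vessel_annotation()].
#' @param thresholds Risk thresholds, see [classify_risk()].
#' @return An object of class `stenosis_measurement`: a list with
#'   `section_id`, `ideal_area_mm2`, `residual_area_mm2`, `percent_residual`,
#'   `percent_occlusion_lo`, and logical flags `hemodynamically_significant`,
#'   `scd_supportive`, `high_risk_plaque`.
#' @examples
#' sq <- function(s) vessel_polygon(c(0, s, s, 0), c(0, 0, s, s))
#' a <- vessel_annotation("demo", sq(1000), region_set(sq(500)),
#'                        microns_per_pixel = 4)
#' measure_stenosis(a) # 16 mm^2 ideal, 4 mm^2 residual, LO = 75
#' @export
measure_stenosis <- function(a, thresholds = risk_thresholds()) {
  if (!inherits(a, "vessel_annotation")) {
    abort_validation("measure_stenosis expects a vessel_annotation")
  }
  f <- mm2_per_px2(a$calibration$microns_per_pixel)
  ideal_px2 <- polygon_area(a$ideal_lumen)
  ideal_mm2 <- ideal_px2 * f
  if (!is.finite(ideal_mm2) || ideal_mm2 <= 0) {
    abort_degenerate("ideal lumen has zero area; cannot measure stenosis")
  }
  res <- clip_regions(canonicalize_regions(a$residual_lumen), a$ideal_lumen)
  residual_mm2 <- region_area(res) * f
  percent_residual <- 100 * residual_mm2 / ideal_mm2
  # clipping guarantees residual <= ideal up to polygon-clipper resolution
  percent_residual <- min(max(percent_residual, 0), 100)
  lo <- 100 - percent_residual
  flags <- classify_risk(lo, residual_mm2, thresholds = thresholds)
  structure(
    c(list(section_id = a$section_id,
           ideal_area_mm2 = ideal_mm2,
           residual_area_mm2 = residual_mm2,
           percent_residual = percent_residual,
           percent_occlusion_lo = lo),
      as.list(flags)),
    class = "stenosis_measurement"
  )
}

#' @export
print.stenosis_measurement <- function(x, ...) {
  cat(sprintf("<stenosis '%s': ideal %.3f mm^2, residual %.3f mm^2, LO %.1f%%>\n",
              x$section_id, x$ideal_area_mm2, x$residual_area_mm2,
              round(x$percent_occlusion_lo, 1)))
  cat(sprintf("  hemodynamically significant (>%g%%): %s | SCD-supportive (>%g%%): %s | high-risk plaque (<%g mm^2): %s\n",
              attr(x, "thresholds")$significant %||% 70, x$hemodynamically_significant,
              attr(x, "thresholds")$scd %||% 75, x$scd_supportive,
              attr(x, "thresholds")$high_risk_area_mm2 %||% 4, x$high_risk_plaque))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default autopsy risk thresholds
#'
#' Occlusion of strictly more than 70% of the lumen is hemodynamically
#' significant; strictly more than 75% supports a diagnosis of sudden
#' cardiac death; a residual patent area strictly smaller than 4 mm^2
#' defines a high-risk plaque.
#'
#' @param significant,scd Percent-occlusion thresholds.
#' @param high_risk_area_mm2 Residual-area threshold in mm^2.
#' @export
risk_thresholds <- function(significant = 70, scd = 75, high_risk_area_mm2 = 4) {
  if (any(!is.finite(c(significant, scd, high_risk_area_mm2))) ||
      any(c(significant, scd, high_risk_area_mm2) <= 0)) {
    abort_validation("risk thresholds must be positive finite numbers")
  }
  list(significant = significant, scd = scd, high_risk_area_mm2 = high_risk_area_mm2)
}

#' Classify stenosis risk
#'
#' All three rules are strict inequalities: `LO > 70` (hemodynamically
#' significant), `LO > 75` (SCD-supportive), `residual < 4 mm^2` (high-risk
#' plaque). A section at exactly LO = 70.0 is therefore *not* significant.
#'
#' @param lo Percent lumen occlusion in `[0, 100]`, or a
#'   `stenosis_measurement` (in which case `residual_area_mm2` is taken from
#'   it).
#' @param residual_area_mm2 Residual patent area in mm^2.
#' @param thresholds See [risk_thresholds()].
#' @return Named logical vector
#'   `c(hemodynamically_significant, scd_supportive, high_risk_plaque)`.
#' @export
classify_risk <- function(lo, residual_area_mm2 = NULL, thresholds = risk_thresholds()) {
  if (inherits(lo, "stenosis_measurement")) {
    residual_area_mm2 <- lo$residual_area_mm2
    lo <- lo$percent_occlusion_lo
  }
  if (is.null(residual_area_mm2)) {
    abort_validation("classify_risk needs residual_area_mm2 when lo is numeric")
  }
  c(hemodynamically_significant = lo > thresholds$significant,
    scd_supportive = lo > thresholds$scd,
    high_risk_plaque = residual_area_mm2 < thresholds$high_risk_area_mm2)
}

#' Tabulate measurements
#'
#' @param measurements A list of `stenosis_measurement` objects.
#' @param digits Decimal places used for the displayed percentage columns
#'   (full precision is retained in the measurement objects themselves).
#' @return A `data.frame`, one row per section.
#' @export
measurement_table <- function(measurements, digits = 1) {
  if (inherits(measurements, "stenosis_measurement")) measurements <- list(measurements)
  df <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(section_id = m$section_id,
               ideal_area_mm2 = m$ideal_area_mm2,
               residual_area_mm2 = m$residual_area_mm2,
               percent_residual = round(m$percent_residual, digits),
               percent_occlusion_lo = round(m$percent_occlusion_lo, digits),
               hemodynamically_significant = m$hemodynamically_significant,
               scd_supportive = m$scd_supportive,
               high_risk_plaque = m$high_risk_plaque,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
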