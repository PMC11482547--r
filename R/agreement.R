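#' Paired eye/digital stenosis series
#'
#' The object the agreement statistics consume: one row per coronary
#' section, with the pathologist's visual estimate (`eye_percent`) and the
#' digital morphometry estimate (`digital_percent`), both in percent lumen
#' occlusion.
#'
#' @param section_id Character vector of unique section identifiers.
#' @param eye_percent,digital_percent Numeric vectors in `[0, 100]`.
#' @return A `data.frame` of subclass `paired_series`.
#' @export
paired_series <- function(section_id, eye_percent, digital_percent) {
  section_id <- as.character(section_id)
  n <- length(section_id)
  if (length(eye_percent) != n || length(digital_percent) != n) {
    abort_validation("section_id, eye_percent and digital_percent must have equal length")
  }
  if (anyDuplicated(section_id)) {
    abort_validation(paste0("duplicate section_id: ",
                            paste(unique(section_id[duplicated(section_id)]), collapse = ", ")))
  }
  for (v in list(eye = eye_percent, digital = digital_percent)) {
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort_validation("stenosis percentages must be finite numbers")
    }
  }
  bad <- eye_percent < 0 | eye_percent > 100 | digital_percent < 0 | digital_percent > 100
  if (any(bad)) {
    abort_validation(paste0("stenosis percentages outside [0, 100] for section(s): ",
                            paste(section_id[bad], collapse = ", ")))
  }
  structure(
    data.frame(section_id = section_id,
               eye_percent = as.numeric(eye_percent),
               digital_percent = as.numeric(digital_percent),
               stringsAsFactors = FALSE),
    class = c("paired_series", "data.frame")
  )
}

check_series <- function(series, min_n = 2L) {
  if (!inherits(series, "paired_series")) {
    if (is.data.frame(series) &&
        all(c("section_id", "eye_percent", "digital_percent") %in% names(series))) {
      series <- paired_series(series$section_id, series$eye_percent, series$digital_percent)
    } else {
      abort_validation("expected a paired_series (section_id, eye_percent, digital_percent)")
    }
  }
  if (nrow(series) < min_n) {
    abort_degenerate(sprintf("need at least %d paired sections, got %d", min_n, nrow(series)),
                     n = nrow(series))
  }
  series
}

pop_var <- function(v) mean((v - mean(v))^2)
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Pearson product-moment correlation of a paired series
#'
#' @param series A [paired_series()].
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(series) {
  series <- check_series(series)
  x <- series$eye_percent
  y <- series$digital_percent
  if (pop_var(x) == 0 || pop_var(y) == 0) {
    abort_degenerate("correlation undefined: a column has zero variance", n = nrow(series))
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 * rho * sigma_x * sigma_y / (sigma_x^2 + sigma_y^2 + (mu_x - mu_y)^2)`,
#' which penalizes both random disagreement (through the Pearson correlation
#' `rho`) and systematic disagreement (through the mean difference and the
#' variance mismatch). Equals 1 only for identical series. The canonical
#' estimator uses population (denominator `n`) variances, Lin's original
#' moment form; `variance = "sample"` gives the `n - 1` variant, which for a
#' 50-pair series differs only in the third decimal.
#'
#' @param series A [paired_series()] (or `x`), with `y` given separately
#'   when `series` is a plain numeric vector.
#' @param y Optional second measurement vector.
#' @param variance `"population"` (default, denominator `n`) or `"sample"`.
#' @return CCC in `[-1, 1]`.
#' @examples
#' lin_ccc(c(0, 1, 2), c(1, 2, 3)) # 4/7: perfect correlation, shifted mean
#' @export
lin_ccc <- function(series, y = NULL, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (!is.null(y)) {
    series <- paired_series(seq_along(y), series, y)
  }
  series <- check_series(series)
  x <- series$eye_percent
  y <- series$digital_percent
  vx <- pop_var(x)
  vy <- pop_var(y)
  if (vx == 0 || vy == 0) {
    abort_degenerate("CCC undefined: a column has zero variance", n = nrow(series))
  }
  sxy <- pop_cov(x, y)
  if (variance == "sample") {
    n <- length(x)
    vx <- vx * n / (n - 1)
    vy <- vy * n / (n - 1)
    sxy <- sxy * n / (n - 1)
  }
  2 * sxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Asymptotic confidence interval for Lin's CCC
#'
#' Fisher z-transform interval: `atanh(ccc)` plus/minus a normal quantile
#' times Lin's asymptotic standard error, back-transformed with `tanh`.
#' The full standard error depends on the Pearson correlation and the
#' standardized location shift `u = (mu_x - mu_y) / sqrt(sigma_x sigma_y)`;
#' when these are not supplied the location-shift-free case (`rho = ccc`,
#' `u = 0`) is used, for which the standard error reduces to
#' `1 / sqrt(n - 2)`.
#'
#' @param ccc The point estimate in `[-1, 1]`.
#' @param n Number of pairs (at least 3).
#' @param level Confidence level in `(0, 1)`.
#' @param pearson Optional Pearson correlation of the underlying series.
#' @param u Optional standardized mean difference of the series.
#' @return Numeric `c(ci_low, ci_high)`; degenerate `(ccc, ccc)` when
#'   `|ccc| = 1`.
#' @export
ccc_confidence_interval <- function(ccc, n, level = 0.95, pearson = NULL, u = NULL) {
  if (!is.finite(ccc) || abs(ccc) > 1) abort_validation("ccc must lie in [-1, 1]")
  if (n < 3) abort_degenerate("confidence interval needs n >= 3", n = as.integer(n))
  if (level <= 0 || level >= 1) abort_validation("level must be in (0, 1)")
  if (abs(ccc) == 1) return(c(ci_low = ccc, ci_high = ccc))
  r <- if (is.null(pearson)) ccc else pearson
  if (is.null(u)) u <- 0
  C2 <- ccc^2
  se2 <- ((1 - r^2) * C2 / ((1 - C2) * r^2) +
            4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - C2)^2) -
            2 * C2^2 * u^4 / (r^2 * (1 - C2)^2)) / (n - 2)
  se <- sqrt(max(se2, 0))
  q <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(ccc)
  c(ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
}

#' Full agreement summary of a paired series
#'
#' Sample size, Pearson correlation, column means and (population)
#' variances, Lin's CCC under both variance conventions, and the asymptotic
#' confidence interval (using the data-dependent standard error).
#'
#' @param series A [paired_series()].
#' @param level Confidence level.
#' @param stratum_label Label carried into reports.
#' @return An object of class `agreement_summary`.
#' @export
agreement_summary <- function(series, level = 0.95, stratum_label = "overall") {
  series <- check_series(series)
  x <- series$eye_percent
  y <- series$digital_percent
  r <- pearson_correlation(series)
  ccc <- lin_ccc(series)
  u <- (mean(x) - mean(y)) / sqrt(sqrt(pop_var(x)) * sqrt(pop_var(y)))
  ci <- if (nrow(series) >= 3 && abs(ccc) < 1) {
    ccc_confidence_interval(ccc, nrow(series), level, pearson = r, u = u)
  } else {
    c(ci_low = ccc, ci_high = ccc)
  }
  structure(
    list(n = nrow(series),
         pearson = r,
         mean_eye = mean(x), mean_digital = mean(y),
         var_eye = pop_var(x), var_digital = pop_var(y),
         ccc = ccc,
         ccc_sample_variance = lin_ccc(series, variance = "sample"),
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         ci_level = level,
         stratum_label = stratum_label),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement '%s': n=%d, pearson=%.3f, CCC=%.3f [%.3f, %.3f] at %d%%>\n",
              x$stratum_label, x$n, x$pearson, x$ccc, x$ci_low, x$ci_high,
              round(100 * x$ci_level)))
  invisible(x)
}

#' Agreement restricted to a critical stenosis stratum
#'
#' Subsets the series to pairs whose designated value(s) lie in
#' `[low, high]` (bounds inclusive) and computes the full
#' [agreement_summary()] on the subset. Which column decides membership is
#' genuinely ambiguous for critical-range analyses, so the rule is explicit:
#' `"eye"` (default), `"digital"`, `"both"`, or `"either"`.
#'
#' @param series A [paired_series()].
#' @param low,high Stratum bounds in percent, `low < high`.
#' @param membership Membership rule.
#' @param level Confidence level.
#' @return An `agreement_summary` labelled with the stratum.
#' @export
stratified_agreement <- function(series, low, high,
                                 membership = c("eye", "digital", "both", "either"),
                                 level = 0.95) {
  membership <- match.arg(membership)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    abort_validation("stratum bounds must satisfy low < high")
  }
  series <- check_series(series)
  keep <- stratum_members(series, low, high, membership)
  sub <- series[keep, , drop = FALSE]
  label <- sprintf("[%g, %g] by %s", low, high, membership)
  if (nrow(sub) < 2) {
    abort_degenerate(sprintf("stratum %s too small for agreement statistics (n = %d)",
                             label, nrow(sub)), n = nrow(sub))
  }
  if (pop_var(sub$eye_percent) == 0 || pop_var(sub$digital_percent) == 0) {
    abort_degenerate(sprintf("stratum %s has a zero-variance column (n = %d)",
                             label, nrow(sub)), n = nrow(sub))
  }
  class(sub) <- class(series)
  agreement_summary(sub, level = level, stratum_label = label)
}

stratum_members <- function(series, low, high, membership) {
  ine <- series$eye_percent >= low & series$eye_percent <= high
  ind <- series$digital_percent >= low & series$digital_percent <= high
  switch(membership,
         eye = ine,
         digital = ind,
         both = ine & ind,
         either = ine | ind)
}

#' Threshold-straddle reclassification analysis
#'
#' Flags the sections whose two estimates fall on opposite sides of (or
#' touch) a clinical decision threshold, i.e. where the two methods disagree
#' on risk classification: a pair is discrepant iff
#' `min(eye, digital) <= threshold <= max(eye, digital)` and the two values
#' differ. `upward` collects sections where the digital estimate is the
#' higher one (digital reclassifies into the critical range), `downward`
#' the converse.
#'
#' @param series A [paired_series()].
#' @param threshold Decision threshold in percent (default 70, the
#'   hemodynamic-significance cut-off).
#' @return An object of class `discrepancy_report` with fields `threshold`,
#'   `discrepant_sections`, `upward`, `downward`.
#' @export
threshold_discrepancies <- function(series, threshold = 70) {
  series <- check_series(series, min_n = 1L)
  lo <- pmin(series$eye_percent, series$digital_percent)
  hi <- pmax(series$eye_percent, series$digital_percent)
  disc <- lo <= threshold & threshold <= hi & series$eye_percent != series$digital_percent
  up <- disc & series$digital_percent > series$eye_percent
  structure(
    list(threshold = threshold,
         discrepant_sections = series$section_id[disc],
         upward = series$section_id[up],
         downward = series$section_id[disc & !up]),
    class = "discrepancy_report"
  )
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("<discrepancies at %g%%: %d section(s); %d upward, %d downward>\n",
              x$threshold, length(x$discrepant_sections),
              length(x$upward), length(x$downward)))
  invisible(x)
}
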