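#' The packaged coronary stenosis study series
#'
#' Fifty coronary artery cross-sections sampled during 11 consecutive
#' autopsies, each with the percent lumen stenosis assessed visually by an
#' expert pathologist ("eye") and by digital morphometry on elastic-stained
#' whole-slide images ("digital"), joined with per-subject metadata (sex,
#' age, cause of death, atherosclerosis class). Digital values are printed
#' at 1-decimal precision, the precision at which the series was published;
#' the source measurements carried more decimals, so summary statistics
#' recomputed from this table can differ from the originally published ones
#' in the last digit (the published digital median, 73.3, already differs
#' from the conventional even-n median of the printed column, 73.2).
#'
#' @return A `data.frame` with columns `subject`, `section`, `eye_percent`,
#'   `digital_percent`, `subject_sex`, `subject_age`, `cause_of_death`,
#'   `atherosclerosis_class`. The published column summaries are attached as
#'   attribute `"published_summary"`.
#' @seealso [coronary_series()] for the paired-series view.
#' @export
coronary_sections <- function() {
  path <- system.file("extdata", "coronary_sections.csv", package = "lumenmetry",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$section), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(nrow(df) == 50, length(unique(df$subject)) == 11)
  attr(df, "published_summary") <- published_summary()
  df
}

# Column summaries as originally published alongside the series; kept so
# reports can surface where a recomputation from the 1-decimal table
# deviates (the digital median).
published_summary <- function() {
  list(
    eye = list(min = 30, max = 99, mean = 70.8, median = 75),
    digital = list(min = 35.2, max = 99, mean = 71.9, median = 73.3)
  )
}

#' The packaged study series as a paired series
#'
#' @return A [paired_series()] of the 50 sections, `section_id` `"1"`..`"50"`,
#'   with the study metadata in attribute `"metadata"` and the published
#'   column summaries in attribute `"published_summary"`.
#' @export
coronary_series <- function() {
  df <- coronary_sections()
  s <- paired_series(df$section, df$eye_percent, df$digital_percent)
  attr(s, "metadata") <- df[, c("subject", "section", "subject_sex", "subject_age",
                                "cause_of_death", "atherosclerosis_class")]
  attr(s, "published_summary") <- attr(df, "published_summary")
  s
}
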