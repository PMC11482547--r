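#' Read a paired eye/digital series from CSV
#'
#' The dialect is comma-separated UTF-8 with a decimal point and header
#' columns `section_id`, `eye_percent`, `digital_percent` (extra columns
#' are ignored). Malformed input is rejected, never coerced: missing
#' columns, non-numeric values, out-of-range percentages and duplicate
#' section ids all raise typed parse errors carrying the offending row.
#'
#' @param path Path to the CSV file.
#' @return A [paired_series()].
#' @export
read_paired_csv <- function(path) {
  if (!file.exists(path)) abort_parse("paired CSV not found", file = path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8"),
    error = function(e) abort_parse(paste0("cannot read CSV: ", conditionMessage(e)),
                                    file = path))
  need <- c("section_id", "eye_percent", "digital_percent")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_parse(paste0("missing column(s): ", paste(missing, collapse = ", ")), file = path)
  }
  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad)) {
      abort_parse(sprintf("non-numeric %s value '%s'", col, v[bad[1]]),
                  file = path, locus = sprintf("row %d", bad[1]))
    }
    oob <- which(out < 0 | out > 100)
    if (length(oob)) {
      abort_parse(sprintf("%s value %s outside [0, 100]", col, v[oob[1]]),
                  file = path, locus = sprintf("row %d", oob[1]))
    }
    out
  }
  ids <- df$section_id
  dup <- which(duplicated(ids))
  if (length(dup)) {
    abort_parse(sprintf("duplicated section_id '%s'", ids[dup[1]]),
                file = path, locus = sprintf("row %d", dup[1]))
  }
  paired_series(ids,
                parse_num(df$eye_percent, "eye_percent"),
                parse_num(df$digital_percent, "digital_percent"))
}

#' Write a paired series to CSV
#'
#' Lossless inverse of [read_paired_csv()].
#'
#' @param series A [paired_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(series, path) {
  series <- check_series(series, min_n = 1L)
  utils::write.csv(as.data.frame(series)[, c("section_id", "eye_percent", "digital_percent")],
                   path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
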