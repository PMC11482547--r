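# Classed conditions so callers (and the CLI) can react to failure modes
# without string-matching messages.

lumen_abort <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "lumen_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

abort_validation <- function(message, ...) {
  lumen_abort(message, "lumen_validation_error", call = sys.call(-1), ...)
}

abort_parse <- function(message, file = NA_character_, locus = NA_character_, ...) {
  lumen_abort(
    paste0(message, if (!is.na(file)) paste0(" [file: ", file, "]"),
           if (!is.na(locus)) paste0(" [at: ", locus, "]")),
    "lumen_parse_error", call = sys.call(-1), file = file, locus = locus, ...
  )
}

abort_degenerate <- function(message, n = NA_integer_, ...) {
  lumen_abort(message, "lumen_degenerate_error", call = sys.call(-1), n = n, ...)
}

abort_generation <- function(message, ...) {
  lumen_abort(message, "lumen_generation_error", call = sys.call(-1), ...)
}

abort_segmentation <- function(message, ...) {
  lumen_abort(message, "lumen_segmentation_error", call = sys.call(-1), ...)
}

abort_usage <- function(message, ...) {
  lumen_abort(message, "lumen_usage_error", call = sys.call(-1), ...)
}
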