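#' Write or read a machine-readable result report
#'
#' Serializes a result bundle -- a named list whose elements are data frames
#' (consensus thresholds, z-score records, verdicts, variance components,
#' recovery summaries) or scalars -- to JSON at full double precision.
#' Display rounding is a presentation concern only: `write_report()` can emit
#' an additional human-readable text rendering next to the JSON, but the JSON
#' itself is never rounded, so `read_report()` recovers the bundle exactly.
#'
#' @param results Named list of data frames and/or scalar values. An empty
#'   list is allowed and yields an empty JSON object.
#' @param path Output path for the JSON file.
#' @param text_path Optional path for a plain-text rendering of the same
#'   bundle (tables formatted with 4 significant digits). `NULL` skips it.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the bundle as a named list with data frames restored as tibbles.
#' @examples
#' tmp <- tempfile(fileext = ".json")
#' write_report(list(n = 456), tmp)
#' read_report(tmp)$n
#' @export
write_report <- function(results, path, text_path = NULL) {
  if (!is.list(results) || (length(results) > 0 && is.null(names(results)))) {
    stop_olfpt("results must be a named list", class = "olfpt_validation_error")
  }
  jsonlite::write_json(
    results, path,
    dataframe = "rows", auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
  )
  if (!is.null(text_path)) {
    lines <- character(0)
    for (nm in names(results)) {
      lines <- c(lines, sprintf("== %s ==", nm))
      el <- results[[nm]]
      if (is.data.frame(el)) {
        lines <- c(lines, utils::capture.output(print.data.frame(
          as.data.frame(lapply(el, function(v) if (is.numeric(v)) signif(v, 4) else v)),
          row.names = FALSE
        )))
      } else {
        lines <- c(lines, paste(format(el, digits = 4), collapse = " "))
      }
      lines <- c(lines, "")
    }
    writeLines(lines, text_path)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop_olfpt(sprintf("file not found: %s", path), class = "olfpt_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(el) if (is.data.frame(el)) tibble::as_tibble(el) else el)
}
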