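#' @keywords internal
measurement_columns <- c(
  "test_id", "participant_id", "component", "replicate",
  "dosed_mass_conc_ug_m3", "measured_odor_conc_oue_m3"
)

#' Validate a table of olfactometric measurements
#'
#' A measurement table holds one row per individual olfactometric
#' determination, keyed by proficiency test, participant, odorant component
#' and replicate. `dosed_mass_conc_ug_m3` is the mass concentration c_ik
#' (ug/m3) dosed into the rig for that measurement; `measured_odor_conc_oue_m3`
#' is the odor concentration x_ik (ou_E/m3) the participant reported. Both
#' must be strictly positive so that log10 transforms are defined.
#'
#' @param x A data frame with columns `test_id`, `participant_id`,
#'   `component` (character), `replicate` (whole number), and the two
#'   concentration columns.
#' @return `x` as a tibble, invisibly unchanged, if valid. Otherwise an error
#'   of class `olfpt_validation_error` (or `olfpt_schema_error` for missing
#'   columns) naming the offending column or row.
#' @examples
#' m <- tibble::tibble(
#'   test_id = "T1", participant_id = "P01", component = "NBU",
#'   replicate = 1L, dosed_mass_conc_ug_m3 = 73800,
#'   measured_odor_conc_oue_m3 = 550
#' )
#' validate_measurements(m)
#' @export
validate_measurements <- function(x) {
  if (!is.data.frame(x)) {
    stop_olfpt("measurements must be a data frame", class = "olfpt_validation_error")
  }
  missing <- setdiff(measurement_columns, names(x))
  if (length(missing) > 0) {
    stop_olfpt(
      sprintf("measurement table is missing column(s): %s", paste(missing, collapse = ", ")),
      class = "olfpt_schema_error"
    )
  }
  x <- tibble::as_tibble(x)
  for (col in c("test_id", "participant_id", "component")) {
    if (!is.character(x[[col]])) {
      stop_olfpt(sprintf("column '%s' must be character", col), class = "olfpt_validation_error")
    }
  }
  if (!is.numeric(x$replicate) || any(x$replicate != as.integer(x$replicate)) ||
      any(x$replicate < 1)) {
    stop_olfpt("column 'replicate' must hold whole numbers >= 1",
               class = "olfpt_validation_error")
  }
  x$replicate <- as.integer(x$replicate)
  for (col in c("dosed_mass_conc_ug_m3", "measured_odor_conc_oue_m3")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      stop_olfpt(sprintf("column '%s' must be numeric", col), class = "olfpt_validation_error")
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop_olfpt(
        sprintf("column '%s' must be finite and > 0 (log10 must be defined); first bad row: %d",
                col, bad[1]),
        class = "olfpt_validation_error"
      )
    }
  }
  key <- paste(x$test_id, x$participant_id, x$component, x$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_olfpt(
      sprintf("duplicate (test_id, participant_id, component, replicate) key at row %d", dup[1]),
      class = "olfpt_validation_error"
    )
  }
  x[measurement_columns]
}

#' Read / write measurement tables
#'
#' The on-disk format is UTF-8 CSV with `.` as decimal separator and the
#' exact header `test_id,participant_id,component,replicate,`
#' `dosed_mass_conc_ug_m3,measured_odor_conc_oue_m3`. Concentrations are
#' written at full double precision, so a write/read round trip is lossless.
#' Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return `read_measurements()` returns a validated tibble of measurements;
#'   `write_measurements()` returns `path` invisibly.
#' @seealso [validate_measurements()] for the invariants enforced on read.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop_olfpt(sprintf("file not found: %s", path), class = "olfpt_io_error")
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      test_id = readr::col_character(),
      participant_id = readr::col_character(),
      component = readr::col_character(),
      replicate = readr::col_integer(),
      dosed_mass_conc_ug_m3 = readr::col_double(),
      measured_odor_conc_oue_m3 = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  validate_measurements(x)
}

#' @param x A measurement table (validated before writing).
#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  x <- validate_measurements(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @keywords internal
stop_olfpt <- function(message, class) {
  stop(structure(
    class = c(class, "olfpt_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
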