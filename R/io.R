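#' Read a long-format measurement CSV
#'
#' Canonical input format: UTF-8 CSV with header
#' `participant,measure,side,week,phase,value`, `.` decimal separator and
#' an empty value field for a missed assessment. Rows with an unknown
#' phase label or a non-numeric week are collected into a validation
#' report (attached as the `"validation"` attribute) and excluded from
#' the returned data — never silently dropped.
#'
#' @param path CSV file path.
#' @return Long tibble (see [generate_series()] for the column contract)
#'   with attribute `"validation"`: a tibble of row-level issues (zero
#'   rows when the file is clean).
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("participant", "measure", "side", "week", "phase", "value")
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  show_col_types = FALSE))
  miss <- setdiff(required, header)
  if (length(miss) > 0) {
    stop("input is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    measure = readr::col_character(),
    side = readr::col_character(),
    week = readr::col_integer(),
    phase = readr::col_character(),
    value = readr::col_double()))
  issues <- list()
  bad_phase <- !raw$phase %in% .phase_levels
  if (any(bad_phase)) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      row = which(bad_phase), issue = "unknown phase label",
      detail = raw$phase[bad_phase])
  }
  bad_week <- is.na(raw$week)
  if (any(bad_week)) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      row = which(bad_week), issue = "missing or non-integer week",
      detail = NA_character_)
  }
  keep <- !bad_phase & !bad_week
  data <- raw[keep, required]
  data$phase <- as_phase(data$phase)
  validation <- if (length(issues) == 0) {
    tibble::tibble(row = integer(), issue = character(), detail = character())
  } else dplyr::bind_rows(issues)
  structure(data, validation = validation)
}

#' Write a long-format measurement CSV
#'
#' Canonical ordering (measure, participant, side, week), fixed six-decimal
#' value precision and an empty field for missing values, so
#' write-read-write round-trips are byte-identical.
#'
#' @param data long tibble.
#' @param path output path.
#' @param digits fixed number of decimals written for values.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path, digits = 6) {
  out <- data[order(data$measure, data$participant, data$side, data$week), ]
  out$phase <- as.character(out$phase)
  out$value <- ifelse(is.na(out$value), NA_character_,
                      formatC(out$value, format = "f", digits = digits))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validation issues of a read dataset
#'
#' @param data result of [read_long_csv()].
#' @return Tibble of issues.
#' @export
validation_report <- function(data) {
  v <- attr(data, "validation")
  if (is.null(v)) tibble::tibble(row = integer(), issue = character(),
                                 detail = character()) else v
}
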