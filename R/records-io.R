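#' Read and write per-fraction record tables
#'
#' Fraction records are tidy CSV tables with one row per
#' (patient, fraction, parameter) measurement and the columns
#' \code{patient_id}, \code{fraction}, \code{parameter}, \code{value},
#' \code{planned_value}. \code{readFractionRecords} validates on read:
#' the parameter label must come from \code{\link{deviationParameters}},
#' fractions must be positive integers, planned values strictly positive,
#' and the (patient, fraction, parameter) key unique. Malformed rows are
#' reported by row number (header = row 1).
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, header required).
#' @param records Data frame of fraction records, as returned by
#'   \code{readFractionRecords} or \code{\link{simulateCohort}}.
#' @return \code{readFractionRecords}: a validated \code{data.frame} of
#'   records. \code{writeFractionRecords}: the path, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' rec <- data.frame(patient_id = "P01", fraction = 1:2, parameter = "GTV",
#'                   value = c(98, 97), planned_value = 100)
#' writeFractionRecords(rec, tmp)
#' readFractionRecords(tmp)
#' @export
readFractionRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  validateFractionRecords(df)
}

#' @rdname readFractionRecords
#' @export
writeFractionRecords <- function(records, path) {
  records <- validateFractionRecords(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Validate (and lightly normalise) a fraction-record table. `data_row_offset`
# converts data indices to file row numbers when reporting errors.
validateFractionRecords <- function(records) {
  required <- c("patient_id", "fraction", "parameter", "value", "planned_value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("fraction records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  if (nrow(records) == 0) {
    records$patient_id <- as.character(records$patient_id)
    records$fraction <- as.integer(records$fraction)
    return(records)
  }
  records$patient_id <- as.character(records$patient_id)
  rowno <- function(i) i + 1L  # header occupies row 1

  bad <- which(!is.finite(records$fraction) | records$fraction < 1 |
                 records$fraction != round(records$fraction))
  if (length(bad)) {
    stop("invalid fraction (must be integer >= 1) at file row(s) ",
         paste(rowno(utils::head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  records$fraction <- as.integer(records$fraction)

  bad <- which(!records$parameter %in% deviationParameters())
  if (length(bad)) {
    stop("unknown parameter label(s) ",
         paste(unique(records$parameter[utils::head(bad, 5)]), collapse = ", "),
         " at file row(s) ", paste(rowno(utils::head(bad, 5)), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(records$value))
  if (length(bad)) {
    stop("non-finite value at file row(s) ",
         paste(rowno(utils::head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$planned_value) | records$planned_value <= 0)
  if (length(bad)) {
    stop("planned_value must be finite and > 0; offending file row(s) ",
         paste(rowno(utils::head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$patient_id, records$fraction, records$parameter,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- dup[1L]
    stop(sprintf(
      "duplicate record for (patient '%s', fraction %d, parameter '%s')",
      records$patient_id[first], records$fraction[first],
      records$parameter[first]), call. = FALSE)
  }
  records
}
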