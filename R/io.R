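# CSV interchange for barn record tables.
#
# One tabular format: RFC 4180 CSV, UTF-8, period decimal.  Required
# environment columns are air_temperature_C, relative_humidity_pct,
# air_velocity_ms; physiology columns are optional.  All temperatures are
# degC in files.

.ENV_COLS <- c("air_temperature_C", "relative_humidity_pct",
               "air_velocity_ms")

#' Read a barn record table
#'
#' Schema-validated CSV reader.  A missing required environment column is a
#' hard error; individual rows failing numeric or range validation
#' (non-numeric cells, relative humidity outside `[0, 100]`, negative air
#' velocity, non-finite temperature) are dropped with a warning, and the
#' rejects are reported with their file line numbers in attribute
#' `"row_errors"`.
#'
#' @param path CSV file path with a header row.
#' @return Data frame of valid records.
#' @export
read_barn_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ENV_COLS, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(
    c(.ENV_COLS, "skin_temperature_C", "respiration_rate_bpm",
      "core_temperature_C", "globe_temperature_C", "floor_temperature_C"),
    names(raw))
  errors <- data.frame(line = integer(), reason = character())
  flag <- function(bad, reason) {
    bad <- which(bad)
    if (length(bad)) {
      # +1 for the header line
      errors <<- rbind(errors, data.frame(line = bad + 1L, reason = reason))
    }
  }
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    flag(is.na(v) & !is.na(raw[[cl]]) & raw[[cl]] != "",
         paste0(cl, " is not numeric"))
    raw[[cl]] <- v
  }
  flag(!is.finite(raw$air_temperature_C), "air_temperature_C missing")
  flag(is.finite(raw$relative_humidity_pct) &
         (raw$relative_humidity_pct < 0 | raw$relative_humidity_pct > 100),
       "relative_humidity_pct out of [0,100]")
  flag(!is.finite(raw$relative_humidity_pct),
       "relative_humidity_pct missing")
  flag(is.finite(raw$air_velocity_ms) & raw$air_velocity_ms < 0,
       "air_velocity_ms negative")
  flag(!is.finite(raw$air_velocity_ms), "air_velocity_ms missing")
  bad_rows <- unique(errors$line - 1L)
  if (length(bad_rows)) {
    warning(length(bad_rows), " row(s) rejected during validation; see ",
            "attr(x, 'row_errors')")
    out <- raw[-bad_rows, , drop = FALSE]
  } else {
    out <- raw
  }
  rownames(out) <- NULL
  attr(out, "row_errors") <- errors[order(errors$line), , drop = FALSE]
  out
}

#' Write a barn record table
#'
#' Plain CSV writer (no row names, full numeric precision) whose output
#' round-trips through [read_barn_table()].
#'
#' @param table Data frame with at least the required environment columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_barn_table <- function(table, path) {
  missing_cols <- setdiff(.ENV_COLS, names(table))
  if (length(missing_cols)) {
    stop("cannot write table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
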