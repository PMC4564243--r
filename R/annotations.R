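#' Read a selection table of call annotations
#'
#' Reads a Raven-style tab-separated selection table delimiting calls in time
#' and frequency. The columns `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`
#' and `High Freq (Hz)` are required; any other columns are preserved. Rows
#' violating `end > begin` or `high > low >= 0` are dropped with a warning that
#' names the row.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `begin_time`, `end_time` (s), `low_freq`,
#'   `high_freq` (Hz), `behaviour_label` (free text, `NA` if absent) and
#'   `source_file`, one row per retained annotation in file order.
#' @export
read_selection_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("selection table is missing required column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    begin_time = as.numeric(raw[["Begin Time (s)"]]),
    end_time = as.numeric(raw[["End Time (s)"]]),
    low_freq = as.numeric(raw[["Low Freq (Hz)"]]),
    high_freq = as.numeric(raw[["High Freq (Hz)"]]),
    behaviour_label = if ("Behaviour" %in% names(raw)) as.character(raw[["Behaviour"]]) else NA_character_,
    source_file = path
  )
  ok <- with(out, end_time > begin_time & high_freq > low_freq & low_freq >= 0 &
               is.finite(begin_time) & is.finite(end_time))
  ok[is.na(ok)] <- FALSE
  if (any(!ok) && nrow(out) > 0) {
    warning("dropped invalid annotation row(s): ", paste(which(!ok), collapse = ", "))
  }
  out[ok, , drop = FALSE]
}

#' Write a selection table
#'
#' Inverse of [read_selection_table()]: writes the conventional tab-separated
#' schema so that a read/write cycle reproduces the file content (modulo line
#' endings, which are normalised to `\n`).
#'
#' @param annotations Tibble as returned by [read_selection_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(annotations, path) {
  df <- data.frame(
    check.names = FALSE,
    `Begin Time (s)` = annotations$begin_time,
    `End Time (s)` = annotations$end_time,
    `Low Freq (Hz)` = annotations$low_freq,
    `High Freq (Hz)` = annotations$high_freq
  )
  if (!all(is.na(annotations$behaviour_label))) df[["Behaviour"]] <- annotations$behaviour_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fixed column order of the measurement table; shared by reader/writer and the
# feature-matrix builder.
measurement_columns <- function() {
  c("min_f", "max_f", "start_f", "end_f", "delta_f", "duration",
    "n_extrema", "n_inflections", "fm_rate", "has_harmonics",
    "sideband_spacing", "call_class")
}

#' Write a call-measurement table to CSV
#'
#' One row per call, columns in the fixed documented order
#' (`min_f, max_f, start_f, end_f, delta_f, duration, n_extrema, n_inflections,
#' fm_rate, has_harmonics, sideband_spacing, call_class`). Frequencies are in
#' kHz and durations in seconds, matching the published tables. A missing
#' sideband spacing (tonal calls) is written as an empty cell, never as 0.
#'
#' @param measurements Tibble of call measurements (see [measure_call()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(measurements, path) {
  if (nrow(measurements) < 1) stop("no measurements to write", call. = FALSE)
  cols <- measurement_columns()
  extra <- setdiff(names(measurements), cols)
  df <- as.data.frame(measurements[, c(cols, extra), drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a call-measurement table written by [write_measurement_table()]
#' @param path CSV path.
#' @return A tibble of measurements; empty sideband cells come back as `NA`.
#' @export
read_measurement_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$has_harmonics <- as.logical(df$has_harmonics)
  df$sideband_spacing <- as.numeric(df$sideband_spacing)
  tibble::as_tibble(df)
}
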