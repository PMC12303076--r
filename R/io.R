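# Serialization of CDM datasets.
#
# Canonical on-disk form: one RFC 4180 CSV per table (UTF-8, header row,
# ISO-8601 dates, "T"-separated second-resolution timestamps, empty cell =
# missing). File names are fixed: patients.csv, trajectories.csv,
# diagnoses.csv, prescriptions.csv, labs.csv, admissions.csv, reports.csv,
# sct.csv, registry.csv. JSON-lines (*.jsonl) is supported as an alternate
# serialization of the same tables. A provenance.json sidecar records the
# generator seed/config digest when present.

format_cdm_column <- function(x, type) {
  switch(type,
    Date = ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d")),
    POSIXct = ifelse(is.na(x), NA_character_,
                     format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    logical = ifelse(is.na(x), NA_character_, ifelse(x, "TRUE", "FALSE")),
    numeric = ifelse(is.na(x), NA_character_,
                     format(x, digits = 15, trim = TRUE, scientific = FALSE)),
    as.character(x)
  )
}

parse_cdm_column <- function(x, type, table, col, file) {
  blank <- is.na(x) | x == ""
  parsed <- switch(type,
    character = ifelse(blank, NA_character_, x),
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = as.logical(toupper(x)),
    Date = as.Date(x, format = "%Y-%m-%d", optional = TRUE),
    POSIXct = as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  bad <- which(!blank & is.na(parsed))
  if (length(bad) > 0) {
    stopf("parse error in %s, column '%s', row %d: cannot interpret '%s' as %s",
          file, col, bad[1], x[bad[1]], type)
  }
  parsed
}

check_prescription_dates <- function(df, file) {
  bad <- which(!is.na(df$end_date) & df$end_date < df$start_date)
  if (length(bad) > 0) {
    stopf("parse error in %s, row %d: end_date (%s) precedes start_date (%s)",
          file, bad[1], format(df$end_date[bad[1]]), format(df$start_date[bad[1]]))
  }
  invisible(df)
}

#' Load a CDM dataset from a directory
#'
#' Reads the fixed-name table files (CSV canonical, JSON-lines alternate)
#' from `path` into a typed [cdm_dataset()]. Missing table files yield empty
#' tables; malformed rows raise a parse error naming the file, column and row.
#' A prescriptions row whose `end_date` precedes its `start_date` is rejected
#' at load time.
#'
#' @param path directory containing the table files.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return a [cdm_dataset()].
#' @export
load_dataset <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stopf("I/O error: directory '%s' does not exist", path)
  schema <- cdm_schema()
  tables <- list()
  for (name in cdm_table_names()) {
    file <- file.path(path, paste0(name, ".", if (format == "csv") "csv" else "jsonl"))
    if (!file.exists(file)) {
      tables[[name]] <- empty_cdm_table(name)
      next
    }
    raw <- tryCatch(
      if (format == "csv") {
        utils::read.csv(file, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), fileEncoding = "UTF-8")
      } else {
        as.data.frame(jsonlite::stream_in(file(file, encoding = "UTF-8"),
                                          verbose = FALSE))
      },
      error = function(e) stopf("I/O error reading '%s': %s", file, conditionMessage(e))
    )
    if (nrow(raw) == 0) {
      tables[[name]] <- empty_cdm_table(name)
      next
    }
    spec <- schema[[name]]
    missing_cols <- setdiff(names(spec), names(raw))
    if (length(missing_cols) > 0) {
      stopf("parse error in %s: missing column(s) %s", file,
            paste(missing_cols, collapse = ", "))
    }
    out <- raw[names(spec)]
    for (col in names(spec)) {
      out[[col]] <- parse_cdm_column(as.character(out[[col]]), spec[[col]],
                                     name, col, file)
    }
    if (name == "prescriptions") check_prescription_dates(out, file)
    tables[[name]] <- coerce_cdm_table(out, name)
  }
  prov_file <- file.path(path, "provenance.json")
  prov <- if (file.exists(prov_file)) jsonlite::read_json(prov_file) else NULL
  cdm_dataset(tables, provenance = prov)
}

#' Write a CDM dataset to a directory
#'
#' Serializes every table under its fixed file name; the round-trip
#' `load_dataset(write_dataset(ds, path))` reproduces `ds` field for field.
#' Empty tables are written as header-only files.
#'
#' @param ds a [cdm_dataset()].
#' @param path output directory (created if needed).
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stopf("I/O error: cannot create directory '%s'", path)
  }
  schema <- cdm_schema()
  for (name in cdm_table_names()) {
    df <- ds[[name]]
    spec <- schema[[name]]
    out <- df
    for (col in names(spec)) {
      out[[col]] <- format_cdm_column(df[[col]], spec[[col]])
    }
    file <- file.path(path, paste0(name, ".", if (format == "csv") "csv" else "jsonl"))
    if (format == "csv") {
      con <- file(file, open = "w", encoding = "UTF-8")
      utils::write.csv(out, con, row.names = FALSE, na = "")
      close(con)
    } else {
      con <- file(file, open = "w", encoding = "UTF-8")
      jsonlite::stream_out(out, con, verbose = FALSE, na = "null")
      close(con)
    }
  }
  prov <- attr(ds, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, file.path(path, "provenance.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}
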