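# Common data model: table schemas, constructor, coercion.
#
# The CDM is a fixed set of nine flat tables into which heterogeneous
# hospital EHR extracts are harmonized. All dates are pure calendar dates
# (class Date); laboratory results and imaging reports carry timestamps
# (POSIXct, UTC, second resolution). Identifiers are opaque strings.

cdm_table_names <- function() {
  c("patients", "trajectories", "diagnoses", "prescriptions", "labs",
    "admissions", "reports", "sct", "registry")
}

cdm_schema <- function() {
  list(
    patients = c(patient_id = "character", birth_year = "integer",
                 sex = "character", resident_nl = "logical"),
    trajectories = c(trajectory_id = "character", patient_id = "character",
                     hospital_id = "character", start_date = "Date",
                     tumor_group = "character"),
    diagnoses = c(patient_id = "character", icd10_code = "character",
                  date = "Date", status = "character",
                  tumor_group = "character"),
    prescriptions = c(patient_id = "character", atc_code = "character",
                      drug_name = "character", dose_mg_per_day = "numeric",
                      start_date = "Date", end_date = "Date"),
    labs = c(patient_id = "character", loinc_code = "character",
             analyte_name = "character", value = "numeric",
             unit = "character", datetime = "POSIXct"),
    admissions = c(patient_id = "character", admit_date = "Date",
                   discharge_date = "Date", main_icd10 = "character",
                   secondary_icd10 = "character", icu = "logical"),
    reports = c(patient_id = "character", datetime = "POSIXct",
                modality = "character", text = "character"),
    sct = c(patient_id = "character", date = "Date", kind = "character"),
    registry = c(patient_id = "character", tumor_group = "character",
                 diagnosis_year = "integer", hospital_id = "character")
  )
}

tumor_groups <- function() c("AML", "MM", "lung", "breast")

empty_cdm_table <- function(name) {
  spec <- cdm_schema()[[name]]
  cols <- lapply(spec, function(type) {
    switch(type,
      character = character(0),
      integer = integer(0),
      numeric = numeric(0),
      logical = logical(0),
      Date = as.Date(character(0)),
      POSIXct = as.POSIXct(character(0), tz = "UTC")
    )
  })
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerce_cdm_table <- function(df, name) {
  spec <- cdm_schema()[[name]]
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols) > 0) {
    stopf("table '%s' is missing column(s): %s", name,
          paste(missing_cols, collapse = ", "))
  }
  df <- df[names(spec)]
  for (col in names(spec)) {
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = as.logical(df[[col]]),
      Date = as.Date(df[[col]]),
      POSIXct = as.POSIXct(df[[col]], tz = "UTC")
    )
  }
  rownames(df) <- NULL
  df
}

#' Construct a CDM dataset
#'
#' Bundles the nine harmonized EHR tables (patients, care trajectories,
#' diagnoses, prescriptions, laboratory results, admissions, imaging
#' reports, stem-cell transplants, registry extract) into a single object.
#' Missing tables default to empty tables; supplied tables are coerced to
#' the schema column types.
#'
#' @param ... named tables; names must be among [cdm_table_names()].
#' @param provenance optional list recording how the dataset was produced
#'   (e.g. generator seed and configuration digest).
#' @return an object of class `cdm_dataset`: a named list of data.frames.
#' @seealso [load_dataset()], [write_dataset()], [validate_dataset()]
#' @export
#' @examples
#' ds <- cdm_dataset()         # all tables empty
#' names(ds)
cdm_dataset <- function(..., provenance = NULL) {
  supplied <- list(...)
  if (length(supplied) == 1 && is.null(names(supplied)) &&
      is.list(supplied[[1]]) && !is.data.frame(supplied[[1]])) {
    supplied <- supplied[[1]]
  }
  unknown <- setdiff(names(supplied), cdm_table_names())
  if (length(unknown) > 0) {
    stopf("unknown CDM table(s): %s", paste(unknown, collapse = ", "))
  }
  tables <- lapply(cdm_table_names(), function(name) {
    if (!is.null(supplied[[name]])) {
      coerce_cdm_table(as.data.frame(supplied[[name]]), name)
    } else {
      empty_cdm_table(name)
    }
  })
  names(tables) <- cdm_table_names()
  structure(tables, provenance = provenance, class = c("cdm_dataset", "list"))
}

#' @export
print.cdm_dataset <- function(x, ...) {
  cat("<cdm_dataset>\n")
  for (name in cdm_table_names()) {
    cat(sprintf("  %-13s %6d rows\n", name, nrow(x[[name]])))
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov$seed)) cat(sprintf("  provenance: seed %s\n", prov$seed))
  invisible(x)
}

# Row-bind a list of partial table rows onto the schema (used by the
# generator); NULL/empty entries are dropped.
bind_cdm_rows <- function(rows, name) {
  rows <- Filter(function(r) !is.null(r) && nrow(r) > 0, rows)
  if (length(rows) == 0) return(empty_cdm_table(name))
  coerce_cdm_table(do.call(rbind, rows), name)
}
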