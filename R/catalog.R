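# Regimen catalogs and the ATC -> drug-class mapping.
#
# A catalog row names a regimen as a set of normalized drug classes plus a
# reporting category; hematopoietic stem-cell transplants are event-based
# entries (matched from the sct table, not from prescriptions). Both files
# are plain CSV and user-replaceable; the shipped versions cover the multiple
# myeloma catalog (with its reporting categories: Anti-CD38, PI-IMID, PI,
# IMID, Bispecific, CAR-T, Other, HSCT) and a starter AML catalog.

#' Load a regimen catalog
#'
#' @param path CSV file with columns `name`, `category`, `drug_classes`
#'   (semicolon-joined), `maintenance_flag`, `event` (empty for drug
#'   regimens; `auto`/`allo` for transplant entries).
#' @return data.frame with an added list-column `classes`.
#' @export
load_regimen_catalog <- function(path) {
  cat <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  needed <- c("name", "category", "drug_classes", "maintenance_flag", "event")
  missing_cols <- setdiff(needed, names(cat))
  if (length(missing_cols) > 0) {
    stopf("catalog '%s' is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cat$name)) {
    stopf("catalog '%s' has duplicate regimen names", path)
  }
  cat$maintenance_flag <- as.logical(toupper(cat$maintenance_flag))
  cat$classes <- split_codes(cat$drug_classes)
  cat$classes <- lapply(cat$classes, function(x) x[x != ""])
  empty_drug <- vapply(cat$classes, length, integer(1)) == 0 & cat$event == ""
  if (any(empty_drug)) {
    stopf("catalog '%s': drug regimen '%s' has no drug classes", path,
          cat$name[which(empty_drug)[1]])
  }
  cat
}

#' @rdname load_regimen_catalog
#' @export
mm_regimen_catalog <- function() {
  load_regimen_catalog(system.file("extdata", "mm_regimen_catalog.csv",
                                   package = "oncocdm", mustWork = TRUE))
}

#' @rdname load_regimen_catalog
#' @export
aml_regimen_catalog <- function() {
  load_regimen_catalog(system.file("extdata", "aml_regimen_catalog.csv",
                                   package = "oncocdm", mustWork = TRUE))
}

#' Load an ATC drug-class mapping
#'
#' Maps WHO ATC codes to the normalized drug classes used by the regimen
#' catalogs. Corticosteroids (dexamethasone, prednisone, prednisolone) share
#' one class, which is what lets a lenalidomide-prednisone episode match the
#' lenalidomide-dexamethasone (Rd) catalog entry.
#'
#' @param path CSV with columns `atc_code`, `drug_class`, `drug_name`,
#'   `default_dose_mg`.
#' @return data.frame.
#' @export
load_drug_map <- function(path) {
  map <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("atc_code", "drug_class", "drug_name", "default_dose_mg")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols) > 0) {
    stopf("drug map '%s' is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is_valid_atc(map$atc_code))
  if (length(bad) > 0) {
    stopf("drug map '%s' row %d: '%s' is not a valid ATC code", path,
          bad[1], map$atc_code[bad[1]])
  }
  map$default_dose_mg <- as.numeric(map$default_dose_mg)
  map
}

#' @rdname load_drug_map
#' @export
default_drug_map <- function() {
  load_drug_map(system.file("extdata", "atc_drug_classes.csv",
                            package = "oncocdm", mustWork = TRUE))
}

#' Normalize a prescription to its drug class
#'
#' Looks a prescription's ATC code up in the drug-class mapping. Codes
#' outside the mapping (antibiotics, antihypertensives, ...) return `NA`
#' and are ignored by episode building.
#'
#' @param atc_code ATC code string (vectorized).
#' @param drug_map mapping from [load_drug_map()].
#' @return character vector of drug classes, `NA` where unmapped.
#' @export
normalize_drug <- function(atc_code, drug_map = default_drug_map()) {
  bad <- which(!is.na(atc_code) & !is_valid_atc(atc_code))
  if (length(bad) > 0) {
    stopf("format error: '%s' is not a valid ATC code", atc_code[bad[1]])
  }
  drug_map$drug_class[match(atc_code, drug_map$atc_code)]
}
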