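# Cross-validation of automatically extracted laboratory items against a
# manually registered copy. Items pair on the exact key (patient, analyte,
# timestamp): a typo in a timestamp therefore surfaces as an unpaired item,
# not as a value mismatch — a documented property of the comparison.

#' Pair laboratory items from two sources
#'
#' Exact-key pairing on (patient_id, loinc_code, datetime). Items present
#' on only one side become `unpaired` verdicts. Duplicate keys within one
#' table are a data error listing the duplicates.
#'
#' @param auto automatically extracted lab table.
#' @param manual manually registered lab table.
#' @return data.frame with one row per key seen on either side:
#'   `patient_id`, `loinc_code`, `datetime`, `auto_value`, `auto_unit`,
#'   `manual_value`, `manual_unit`, `side` ("both"/"auto_only"/"manual_only").
#' @export
pair_items <- function(auto, manual) {
  key_of <- function(df) {
    paste(df$patient_id, df$loinc_code,
          format(df$datetime, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), sep = "\r")
  }
  for (nm in c("auto", "manual")) {
    df <- if (nm == "auto") auto else manual
    k <- key_of(df)
    dup <- unique(k[duplicated(k)])
    if (length(dup) > 0) {
      stopf("data error: duplicate key(s) in %s table: %s", nm,
            paste(gsub("\r", "/", utils::head(dup, 3)), collapse = "; "))
    }
  }
  ka <- key_of(auto)
  km <- key_of(manual)
  keys <- sort(union(ka, km))
  ia <- match(keys, ka)
  im <- match(keys, km)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(parts, `[`, character(1), 1),
    loinc_code = vapply(parts, `[`, character(1), 2),
    datetime = as.POSIXct(vapply(parts, `[`, character(1), 3),
                          format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    auto_value = auto$value[ia],
    auto_unit = auto$unit[ia],
    manual_value = manual$value[im],
    manual_unit = manual$unit[im],
    stringsAsFactors = FALSE
  )
  out$side <- ifelse(!is.na(ia) & !is.na(im), "both",
                     ifelse(!is.na(ia), "auto_only", "manual_only"))
  out
}

#' Compare paired laboratory items
#'
#' Units are checked first, then values, with exact numeric equality by
#' default (any typographical perturbation must be caught). The report
#' carries the mismatch percentage in three forms: exact, rounded half-up
#' to 2 decimals, and a display value rounded conservatively upward at the
#' second decimal so a nonzero mismatch rate is never understated.
#'
#' @param pairs data.frame from [pair_items()].
#' @param value_tolerance absolute tolerance for value equality (default 0,
#'   i.e. exact).
#' @return list with `n_pairs`, `n_mismatch`, `pct_exact`, `pct_2dec`,
#'   `pct_display`, `n_unpaired` and the per-pair `verdicts` data.frame
#'   (verdict one of match / value_mismatch / unit_mismatch / unpaired).
#' @export
compare_pairs <- function(pairs, value_tolerance = 0) {
  verdict <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$side[i] != "both") {
      verdict[i] <- "unpaired"
    } else if (!identical(pairs$auto_unit[i], pairs$manual_unit[i])) {
      verdict[i] <- "unit_mismatch"
    } else if (abs(pairs$auto_value[i] - pairs$manual_value[i]) > value_tolerance) {
      verdict[i] <- "value_mismatch"
    } else {
      verdict[i] <- "match"
    }
  }
  pairs$verdict <- verdict
  n_pairs <- sum(pairs$side == "both")
  n_mismatch <- sum(verdict %in% c("value_mismatch", "unit_mismatch"))
  pct <- if (n_pairs > 0) 100 * n_mismatch / n_pairs else 0
  list(
    n_pairs = n_pairs,
    n_mismatch = n_mismatch,
    pct_exact = pct,
    pct_2dec = round_half_up(pct, 2),
    pct_display = pct_ceiling2(pct),
    n_unpaired = sum(verdict == "unpaired"),
    verdicts = pairs
  )
}
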