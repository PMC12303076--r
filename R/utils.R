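#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for every printed percentage in the accuracy tables
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(94.716)  # 95
#' round_half_up(0.4144, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Conservative display rounding for mismatch percentages: ceiling at two
# decimals, so a nonzero discrepancy rate is never displayed smaller than it
# is (0.4144 -> 0.42; exact multiples are unchanged).
pct_ceiling2 <- function(x) ceiling(x * 100 - 1e-9) / 100

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accuracy as integer percent, NA when nothing was predicted.
accuracy_pct <- function(n_correct, n_predicted) {
  ifelse(n_predicted > 0, round_half_up(100 * n_correct / n_predicted), NA_real_)
}

split_codes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), trimws)
}

join_codes <- function(x) vapply(x, paste, character(1), collapse = ";")

# Regex for the coding systems used across the model. ATC codes are accepted
# at the 3-, 5- and 7-character levels.
icd10_regex <- "^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$"
atc_regex <- "^[A-Z][0-9]{2}([A-Z]{2}([0-9]{2})?)?$"

is_valid_icd10 <- function(x) grepl(icd10_regex, x)
is_valid_atc <- function(x) grepl(atc_regex, x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
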