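# Calendar conventions used throughout: 365.25 days per year, months
# converted with the mean Gregorian month length.
DAYS_PER_YEAR <- 365.25

years_to_days <- function(y) y * DAYS_PER_YEAR

#' Convert whole months to days
#'
#' Months are converted with the mean Gregorian month length
#' (30.4375 days) and rounded to the nearest whole day, so the 12- and
#' 24-month surveillance offsets become 365 and 731 days.
#'
#' @param m Number of months (numeric).
#' @return Integer days.
#' @export
months_to_days <- function(m) {
  as.integer(round(m * 30.4375))
}

# Round-half-up at `digits` decimals, matching how epidemiological tables
# are conventionally printed (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Completed years between two dates (floor convention).
age_completed_years <- function(birth_date, at_date) {
  as.integer(floor(as.numeric(at_date - birth_date) / DAYS_PER_YEAR))
}

stop_field <- function(field, msg) {
  abort(sprintf("Invalid `%s`: %s", field, msg), class = "recurrisk_config_error")
}

check_weights <- function(w, field, levels = NULL) {
  if (!is.numeric(w) || any(w < 0)) {
    stop_field(field, "weights must be nonnegative numbers")
  }
  if (abs(sum(w) - 1) > 1e-6) {
    stop_field(field, sprintf("weights must sum to 1 (got %.6f)", sum(w)))
  }
  if (!is.null(levels) && !setequal(names(w), levels)) {
    stop_field(field, paste0("names must be {", paste(levels, collapse = ", "), "}"))
  }
  invisible(w)
}

check_date <- function(x, field) {
  if (!inherits(x, "Date") || anyNA(x)) {
    stop_field(field, "must be a non-missing Date")
  }
  invisible(x)
}

#' @noRd
as_date_col <- function(x) as.Date(x)

SUBTYPE_LEVELS <- c("HR+/HER2-", "HER2+", "TN", "not_available")
STAGE_LEVELS <- c("I", "II", "III", "IV", "missing")
MARKER_LEVELS <- c("positive", "negative", "missing")
EVENT_LEVELS <- c("recurrence", "second_primary", "death", "emigration", "admin_censor")
AGE_BANDS_FIVE <- c("20-39", "40-49", "50-59", "60-69", "70-74")
AGE_BANDS_FOUR <- c("20-39", "40-49", "50-69", "70-74")
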