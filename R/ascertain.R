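#' Default ICD-9-CM indicator code set
#'
#' The four recurrence-indicator classes are defined by ICD-9-CM code
#' prefixes (codes stored without dots): class 1, restart of chemotherapy
#' (procedure 99.25, V58.1x encounters); class 2, restart of radiotherapy
#' (procedures 92.2x, V58.0 encounters); class 3, breast surgery
#' (mastectomy, procedures 85.4x) or admission for malignant breast
#' neoplasm (174.x); class 4, admission for secondary malignant neoplasm
#' (196.x-198.x).  The code set is data, not logic: supply your own list
#' or a YAML file via [read_code_set()] to match a local coding practice.
#'
#' @return Named list of four character vectors of code prefixes.
#' @export
default_code_set <- function() {
  list(
    class1_chemotherapy = c("9925", "V581"),
    class2_radiotherapy = c("922", "V580"),
    class3_breast_surgery_or_malignant_breast = c("854", "174"),
    class4_secondary_malignant_neoplasm = c("196", "197", "198")
  )
}

#' Read an indicator code set from YAML
#'
#' @param path YAML file with the four named classes of
#'   [default_code_set()], each a list of code prefixes.
#' @return Named list of four character vectors.
#' @export
read_code_set <- function(path) {
  cs <- yaml::read_yaml(path)
  validate_code_set(cs)
}

validate_code_set <- function(cs) {
  need <- names(default_code_set())
  if (!all(need %in% names(cs))) {
    abort(paste("Code set must define classes:", paste(need, collapse = ", ")))
  }
  cs <- lapply(cs[need], as.character)
  if (any(vapply(cs, length, 1L) == 0) || any(unlist(cs) == "")) {
    abort("Code-set prefixes must be non-empty")
  }
  cs
}

#' Surveillance start offset in months
#'
#' Recurrence indicators are only counted from 12 months after diagnosis
#' for HER2-negative tumours, or 24 months for HER2-positive tumours,
#' absorbing primary treatment plus a disease-free interval.  Tumours with
#' missing HER2 use the 12-month default.  The sensitivity setting applies
#' the 12-month cutoff to every subtype.
#'
#' @param her2 Character vector over `"positive"`/`"negative"`/`"missing"`.
#' @param sensitivity_12m Apply 12 months to all subtypes.
#' @return Integer months, vectorised over `her2`.
#' @export
surveillance_start <- function(her2, sensitivity_12m = FALSE) {
  if (!all(her2 %in% MARKER_LEVELS)) {
    abort("`her2` must be one of positive/negative/missing")
  }
  if (isTRUE(sensitivity_12m)) {
    rep(12L, length(her2))
  } else {
    ifelse(her2 == "positive", 24L, 12L)
  }
}

# ICD-9-CM lexical form: 3-5 characters, optional leading V or E, digits.
is_valid_code <- function(code) {
  nchar(code) >= 3 & nchar(code) <= 5 & grepl("^[VE]?[0-9]+$", code)
}

#' Assemble a tidy claims table from the two administrative sources
#'
#' Converts the hospital-discharge (HDD) and outpatient-services (OPS)
#' tables into one row per claim with a list-column of its ICD-9-CM codes.
#' The HDD claim date is the admission date; HDD diagnosis and procedure
#' codes (`;`-separated in the raw table) are pooled.  The OPS claim date
#' is the service date with its single service code.
#'
#' @param hdd Tibble with `patient_id`, `admission_date`, `discharge_date`,
#'   `diagnosis_codes`, `procedure_codes`.
#' @param ops Tibble with `patient_id`, `service_date`, `service_code`.
#' @return Tibble with `patient_id`, `source`, `claim_date`, `codes`
#'   (list of character).
#' @export
collect_claims <- function(hdd, ops) {
  split_codes <- function(dx, pr) {
    dx <- ifelse(is.na(dx), "", dx)
    pr <- ifelse(is.na(pr), "", pr)
    map2(strsplit(dx, ";"), strsplit(pr, ";"), \(a, b) {
      out <- c(a, b)
      out[!is.na(out) & out != ""]
    })
  }
  h <- tibble(
    patient_id = hdd$patient_id,
    source = "HDD",
    claim_date = as_date_col(hdd$admission_date),
    codes = split_codes(
      as.character(hdd$diagnosis_codes),
      as.character(hdd$procedure_codes)
    )
  )
  o <- tibble(
    patient_id = ops$patient_id,
    source = "OPS",
    claim_date = as_date_col(ops$service_date),
    codes = map(as.character(ops$service_code), \(x) x[!is.na(x) & x != ""])
  )
  bind_rows(h, o) |> arrange(.data$patient_id, .data$claim_date)
}

# Lowest matching indicator class for one claim's codes, NA when none.
# Malformed codes are dropped (the caller warns once per batch).
match_claim_class <- function(codes, prefixes_by_class) {
  for (k in seq_along(prefixes_by_class)) {
    for (p in prefixes_by_class[[k]]) {
      m <- startsWith(codes, p)
      if (any(m)) return(list(class = k, code = codes[m][1]))
    }
  }
  list(class = NA_integer_, code = NA_character_)
}

#' Match recurrence-indicator claims for one patient
#'
#' Flags every claim on or after the surveillance start whose codes match
#' an indicator class.  A claim carrying codes of several classes is
#' reported once, under the lowest class number.  Claims strictly before
#' `start_date` never match; malformed code strings are skipped with a
#' warning.
#'
#' @param claims Tidy claims tibble for a single patient
#'   (see [collect_claims()]).
#' @param code_set Named list as [default_code_set()].
#' @param start_date Surveillance start date (inclusive).
#' @return Tibble `(patient_id, claim_date, indicator_class, matched_code)`
#'   sorted by `(claim_date, indicator_class)`.
#' @export
match_indicators <- function(claims, code_set = default_code_set(), start_date) {
  code_set <- validate_code_set(code_set)
  claims <- filter(claims, .data$claim_date >= start_date)
  if (nrow(claims) == 0) {
    return(tibble(
      patient_id = character(), claim_date = as.Date(character()),
      indicator_class = integer(), matched_code = character()
    ))
  }
  n_bad <- 0L
  hits <- map(claims$codes, \(codes) {
    codes <- as.character(codes)
    ok <- is_valid_code(codes)
    n_bad <<- n_bad + sum(!ok)
    match_claim_class(codes[ok], code_set)
  })
  if (n_bad > 0) {
    warn(sprintf("Skipped %d malformed ICD-9-CM code(s)", n_bad))
  }
  out <- tibble(
    patient_id = claims$patient_id,
    claim_date = claims$claim_date,
    indicator_class = map_int(hits, "class"),
    matched_code = map_chr(hits, "code")
  ) |>
    filter(!is.na(.data$indicator_class)) |>
    arrange(.data$claim_date, .data$indicator_class)
  out
}

#' Ascertain recurrence dates for a cohort from claims
#'
#' Applies the four-indicator algorithm to every woman: her surveillance
#' window opens 12 months (HER2-negative or missing) or 24 months
#' (HER2-positive) after diagnosis — the boundary day included — and the
#' recurrence date is the date of her earliest indicator claim at or after
#' that boundary.  Women with no qualifying claim are absent from the
#' result.
#'
#' @param cohort Cohort tibble with `patient_id`, `diagnosis_date`,
#'   `her2_status`.
#' @param claims Tidy claims tibble ([collect_claims()]), any number of
#'   patients.
#' @param code_set Named list as [default_code_set()].
#' @param sensitivity_12m Use the uniform 12-month window.
#' @return Tibble `(patient_id, recurrence_date, indicator_class,
#'   matched_code)`, one row per detected woman.
#' @export
ascertain_recurrence <- function(cohort, claims,
                                 code_set = default_code_set(),
                                 sensitivity_12m = FALSE) {
  code_set <- validate_code_set(code_set)
  start_days <- months_to_days(
    surveillance_start(cohort$her2_status, sensitivity_12m)
  )
  starts <- tibble(
    patient_id = cohort$patient_id,
    start_date = cohort$diagnosis_date + start_days
  )
  cl <- claims |>
    inner_join(starts, by = "patient_id") |>
    filter(.data$claim_date >= .data$start_date)
  if (nrow(cl) == 0) {
    return(tibble(
      patient_id = character(), recurrence_date = as.Date(character()),
      indicator_class = integer(), matched_code = character()
    ))
  }
  n_bad <- 0L
  hits <- map(cl$codes, \(codes) {
    codes <- as.character(codes)
    ok <- is_valid_code(codes)
    n_bad <<- n_bad + sum(!ok)
    match_claim_class(codes[ok], code_set)
  })
  if (n_bad > 0) warn(sprintf("Skipped %d malformed ICD-9-CM code(s)", n_bad))
  cl |>
    mutate(
      indicator_class = map_int(hits, "class"),
      matched_code = map_chr(hits, "code")
    ) |>
    filter(!is.na(.data$indicator_class)) |>
    arrange(.data$patient_id, .data$claim_date, .data$indicator_class) |>
    group_by(.data$patient_id) |>
    slice(1) |>
    ungroup() |>
    select(
      "patient_id",
      recurrence_date = "claim_date", "indicator_class", "matched_code"
    )
}

#' Resolve each woman's first-event outcome
#'
#' The outcome is the earliest among the ascertained recurrence date, the
#' registry's second-primary date, the death date, the emigration date and
#' the administrative cutoff.  Same-day ties resolve by the priority
#' recurrence > second primary > death > emigration > administrative
#' censoring: a recurrence claim on the day of death implies the event
#' preceded death within the day's resolution.
#'
#' @param cohort Cohort tibble with `patient_id`, `diagnosis_date`,
#'   `second_primary_date`, `death_date`, `emigration_date`.
#' @param recurrences Output of [ascertain_recurrence()].
#' @param admin_cutoff End-of-follow-up date.
#' @return Tibble `(patient_id, event, time_days, indicator_class)`, one
#'   row per cohort member.
#' @export
resolve_outcomes <- function(cohort, recurrences, admin_cutoff) {
  x <- cohort |>
    left_join(
      select(recurrences, "patient_id", "recurrence_date", "indicator_class"),
      by = "patient_id"
    )
  cand <- cbind(
    as.numeric(x$recurrence_date - x$diagnosis_date),
    as.numeric(x$second_primary_date - x$diagnosis_date),
    as.numeric(x$death_date - x$diagnosis_date),
    as.numeric(x$emigration_date - x$diagnosis_date),
    as.numeric(admin_cutoff - x$diagnosis_date)
  )
  for (j in 1:4) {
    neg <- !is.na(cand[, j]) & cand[, j] < 0
    if (any(neg)) {
      field <- c(
        "recurrence_date", "second_primary_date",
        "death_date", "emigration_date"
      )[j]
      abort(sprintf(
        "`%s` precedes the diagnosis date for patient %s",
        field, x$patient_id[which(neg)[1]]
      ))
    }
  }
  cand[is.na(cand)] <- Inf
  # max.col with ties "first" encodes the event-priority order
  pick <- max.col(-cand, ties.method = "first")
  tibble(
    patient_id = x$patient_id,
    event = EVENT_LEVELS[pick],
    time_days = as.integer(cand[cbind(seq_len(nrow(x)), pick)]),
    indicator_class = ifelse(pick == 1L, x$indicator_class, NA_integer_)
  )
}
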