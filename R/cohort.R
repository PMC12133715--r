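#' Surrogate intrinsic subtype from immunohistochemical markers
#'
#' Classifies each tumour from its ER, PR and HER2 status: HER2-positive
#' tumours are `HER2+` whatever the hormone receptors; HER2-negative
#' tumours with ER or PR positivity are `HR+/HER2-`; HER2-negative
#' tumours with both receptors negative are `TN` (triple negative); any
#' remaining combination (missing markers that leave the class undecided)
#' is `not_available`.
#'
#' @param er,pr,her2 Character vectors over
#'   `"positive"`/`"negative"`/`"missing"`, recycled to common length.
#' @return Character vector over
#'   `c("HR+/HER2-", "HER2+", "TN", "not_available")`.
#' @export
#' @examples
#' assign_subtype("positive", "negative", "negative")
#' assign_subtype("negative", "negative", "positive")
assign_subtype <- function(er, pr, her2) {
  args <- vctrs::vec_recycle_common(er = er, pr = pr, her2 = her2)
  er <- args$er; pr <- args$pr; her2 <- args$her2
  bad <- !(er %in% MARKER_LEVELS) | !(pr %in% MARKER_LEVELS) |
    !(her2 %in% MARKER_LEVELS)
  if (any(bad)) {
    abort("Marker status must be one of positive/negative/missing")
  }
  case_when(
    her2 == "positive" ~ "HER2+",
    her2 == "negative" & (er == "positive" | pr == "positive") ~ "HR+/HER2-",
    her2 == "negative" & er == "negative" & pr == "negative" ~ "TN",
    .default = "not_available"
  )
}

exclusion_criteria <- function() {
  c(
    prior_cancer = "Prior cancer before breast cancer (except C44)",
    synchronous_cancer = "Synchronous cancer (except C44)",
    dco_or_autopsy = "Diagnosis by autopsy or death certificate only",
    no_survival_time = "No survival time",
    death_within_6m = "Death within 6 months of diagnosis",
    missing_stage = "Missing stage",
    stage_iv = "Stage IV (de novo metastatic)",
    age_over_74 = "Older than 74 years at diagnosis"
  )
}

is_c44 <- function(site) !is.na(site) & startsWith(site, "C44")

# Each predicate returns TRUE where the record violates the criterion.
exclusion_predicates <- function(r) {
  age <- age_completed_years(r$birth_date, r$diagnosis_date)
  sync_site <- if ("synchronous_cancer_site" %in% names(r)) {
    r$synchronous_cancer_site
  } else {
    rep(NA_character_, nrow(r))
  }
  list(
    prior_cancer = !is.na(r$prior_cancer_date) & !is_c44(r$prior_cancer_site),
    synchronous_cancer = r$synchronous_cancer_flag & !is_c44(sync_site),
    dco_or_autopsy = r$dco_or_autopsy_flag,
    no_survival_time = !is.na(r$death_date) & r$death_date == r$diagnosis_date,
    death_within_6m = !is.na(r$death_date) &
      as.numeric(r$death_date - r$diagnosis_date) < 183,
    missing_stage = is.na(r$stage_tnm) | r$stage_tnm == "missing",
    stage_iv = !is.na(r$stage_tnm) & r$stage_tnm == "IV",
    age_over_74 = age > 74L
  )
}

#' Apply the registry eligibility cascade
#'
#' Removes women sequentially under eight ordered criteria — prior cancer
#' (except non-melanoma skin cancer C44), synchronous cancer (except C44),
#' diagnosis by autopsy/death certificate only, no survival time (death on
#' the diagnosis date), death within 6 months of diagnosis, missing stage,
#' stage IV, and age over 74 at diagnosis.  Each woman is counted against
#' the first criterion she matches, so the per-criterion counts depend on
#' the order while the final cohort does not.
#'
#' @param records Registry tibble (see [registry_skeleton()] for the schema).
#' @param reference_end End of follow-up; recorded on the log.
#' @return A list with `cohort` (eligible rows) and `log`, a tibble of
#'   `(criterion, label, n_removed)` carrying `initial`/`final` counts as
#'   attributes (class `exclusion_log`).
#' @export
apply_eligibility <- function(records, reference_end = as.Date("2021-12-31")) {
  records <- as_tibble(records)
  dup <- records$patient_id[duplicated(records$patient_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate patient_id in registry: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  crit <- exclusion_criteria()
  n0 <- nrow(records)
  removed <- integer(length(crit))
  names(removed) <- names(crit)
  keep <- records
  if (n0 > 0) {
    preds <- exclusion_predicates(records)
    hit <- rep(NA_character_, n0)
    for (cn in names(crit)) {
      p <- preds[[cn]] & is.na(hit)
      hit[p] <- cn
    }
    removed <- map_int(names(crit), \(cn) sum(hit == cn, na.rm = TRUE)) |>
      setNames(names(crit))
    keep <- records[is.na(hit), ]
  }
  log <- tibble(
    criterion = names(crit),
    label = unname(crit),
    n_removed = unname(removed[names(crit)])
  )
  attr(log, "initial") <- n0
  attr(log, "final") <- nrow(keep)
  attr(log, "reference_end") <- reference_end
  class(log) <- c("exclusion_log", class(log))
  stopifnot(n0 - sum(log$n_removed) == nrow(keep))
  list(cohort = keep, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Eligibility cascade: %d -> %d women\n",
              attr(x, "initial"), attr(x, "final")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  - %-45s %6d removed\n", x$label[i], x$n_removed[i]))
  }
  invisible(x)
}

age_band_five <- function(age) {
  cut(age,
    breaks = c(20, 40, 50, 60, 70, 75), right = FALSE,
    labels = AGE_BANDS_FIVE
  ) |> as.character()
}

age_band_four <- function(age) {
  cut(age,
    breaks = c(20, 40, 50, 70, 75), right = FALSE,
    labels = AGE_BANDS_FOUR
  ) |> as.character()
}

diagnosis_period <- function(diagnosis_date) {
  ifelse(as.integer(format(diagnosis_date, "%Y")) <= 2006,
    "2004-2006", "2007-2010"
  )
}

#' Derive analysis strata for an eligible cohort
#'
#' Adds age at diagnosis (completed years), age band, period of diagnosis
#' (2004-2006 vs 2007-2010), stage and surrogate subtype to an eligible
#' registry table.  Two age groupings are in use in this analysis: a
#' five-band one (20-39/40-49/50-59/60-69/70-74) for descriptive tables
#' and a four-band one merging 50-69 for incidence strata; both are
#' derivable, selected by `age_bands`.
#'
#' @param cohort Eligible registry tibble.
#' @param age_bands `"five"` (default) or `"four"`.
#' @return The cohort with columns `age`, `age_group`, `period`, `stage`,
#'   `subtype` appended.
#' @export
derive_strata <- function(cohort, age_bands = c("five", "four")) {
  age_bands <- match.arg(age_bands)
  age <- age_completed_years(cohort$birth_date, cohort$diagnosis_date)
  if (length(age) > 0 && (any(age < 20) || any(age > 74))) {
    abort("Age at diagnosis outside 20-74: records should have been excluded")
  }
  cohort |>
    mutate(
      age = age,
      age_group = if (age_bands == "five") age_band_five(age) else age_band_four(age),
      period = diagnosis_period(.data$diagnosis_date),
      stage = .data$stage_tnm,
      subtype = assign_subtype(.data$er_status, .data$pr_status, .data$her2_status)
    )
}
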