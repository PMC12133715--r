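STATUS_LEVELS <- c(
  "alive_event_free", "alive_after_recurrence", "alive_after_second_tumour",
  "dead_without_recurrence", "dead_after_recurrence", "dead_after_second_tumour"
)

#' Follow-up status at a fixed horizon
#'
#' Classifies every woman into one of six mutually exclusive states at
#' `horizon_years` after diagnosis.  The pathway is her first event before
#' the horizon (recurrence, second primary, or none); vital status at the
#' horizon splits each pathway into alive/dead.  Events and deaths on or
#' after the horizon are ignored: a woman dying at 11 years after a
#' 3-year recurrence counts as alive after recurrence at 10 years.  Deaths
#' without a preceding ascertained recurrence — including progression with
#' no disease-free interval — fall in `dead_without_recurrence`.  Women
#' emigrating before the horizon are carried at their last known vital
#' status.
#'
#' @param outcomes Tibble with `patient_id`, `event`, `time_days`
#'   ([resolve_outcomes()]) and `death_time_days` (days from diagnosis to
#'   death, NA if alive at end of follow-up).
#' @param horizon_years Horizon, default 10.
#' @return Tibble `(patient_id, state)` with `state` over the six levels.
#' @export
status_at_10y <- function(outcomes, horizon_years = 10) {
  need <- c("patient_id", "event", "time_days", "death_time_days")
  if (!all(need %in% names(outcomes))) {
    abort(paste("`outcomes` must have columns", paste(need, collapse = ", ")))
  }
  bad <- outcomes$event == "death" & is.na(outcomes$death_time_days)
  if (any(bad)) {
    abort(sprintf(
      "Patient %s has a death outcome but no death time",
      outcomes$patient_id[which(bad)[1]]
    ))
  }
  h <- years_to_days(horizon_years)
  dead <- !is.na(outcomes$death_time_days) & outcomes$death_time_days < h
  rec <- outcomes$event == "recurrence" & outcomes$time_days < h
  sp <- outcomes$event == "second_primary" & outcomes$time_days < h
  state <- case_when(
    rec & dead ~ "dead_after_recurrence",
    rec & !dead ~ "alive_after_recurrence",
    sp & dead ~ "dead_after_second_tumour",
    sp & !dead ~ "alive_after_second_tumour",
    dead ~ "dead_without_recurrence",
    .default = "alive_event_free"
  )
  tibble(patient_id = outcomes$patient_id, state = state)
}

#' Stratified status table
#'
#' Counts and percentages of the six follow-up states inside each level of
#' each requested stratum, plus an overall row.  Percentages use the
#' stratum size as denominator and are rounded half-up to one decimal.
#'
#' @param cohort Cohort tibble carrying the stratum columns.
#' @param statuses Output of [status_at_10y()].
#' @param strata Character vector of stratum column names.
#' @return Tibble `(stratum, level, state, n, pct)`.
#' @export
tabulate_status <- function(cohort, statuses,
                            strata = c("age_group", "stage", "subtype")) {
  x <- inner_join(statuses, cohort, by = "patient_id")
  if (nrow(x) != nrow(statuses)) {
    abort("Every status must match exactly one cohort row")
  }
  one <- function(stratum, labels) {
    tibble(level = labels, state = x$state) |>
      filter(!is.na(.data$level)) |>
      count(.data$level, .data$state, name = "n") |>
      tidyr::complete(
        level = unique(labels[!is.na(labels)]),
        state = STATUS_LEVELS,
        fill = list(n = 0L)
      ) |>
      group_by(.data$level) |>
      mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
      ungroup() |>
      mutate(stratum = stratum, .before = 1)
  }
  overall <- one("all", rep("all", nrow(x)))
  per <- map(strata, \(s) {
    if (!s %in% names(x)) abort(sprintf("No stratum column `%s`", s))
    one(s, as.character(x[[s]]))
  })
  bind_rows(overall, list_rbind(per)) |>
    mutate(state = factor(.data$state, levels = STATUS_LEVELS)) |>
    arrange(.data$stratum, .data$level, .data$state) |>
    mutate(state = as.character(.data$state))
}

#' Conditional probability of remaining alive with recurrence
#'
#' Among women alive with a prior ascertained recurrence at `t0` years,
#' the proportion still alive (with that recurrence) at `t1` years.
#'
#' @param outcomes As for [status_at_10y()].
#' @param t0,t1 Years since diagnosis, `t0 < t1`.
#' @return Single probability; NA with a warning when no woman is alive
#'   with recurrence at `t0`.
#' @export
conditional_alive_with_recurrence <- function(outcomes, t0, t1) {
  if (t0 >= t1) abort("`t0` must be strictly less than `t1`")
  alive_with_rec <- function(t) {
    h <- years_to_days(t)
    outcomes$event == "recurrence" & outcomes$time_days < h &
      (is.na(outcomes$death_time_days) | outcomes$death_time_days >= h)
  }
  at0 <- alive_with_rec(t0)
  if (sum(at0) == 0) {
    warn("No woman alive with recurrence at t0: probability undefined")
    return(NA_real_)
  }
  sum(at0 & alive_with_rec(t1)) / sum(at0)
}
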